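# Pipeline orchestration and report writing. The exported R functions are
# the interface: a configuration object drives the stage sequence
# (simulate/load -> call-response -> scan-coevents -> drug-assoc -> lineage
# -> cluster) and every report table is written in a self-verifiable TSV
# layout (each row carries the counts its p-value is computed from).

#' Pipeline configuration
#'
#' Either a [panel_config()] (synthetic input) or paths to mutation /
#' copy-number / lineage / screen TSVs, plus the stage parameters.
#'
#' @param panel Optional [panel_config()]; when given, inputs are simulated.
#' @param mutations,copy_numbers,lineage,screens Input TSV paths (used when
#'   `panel` is `NULL`; `copy_numbers` optional).
#' @param out_dir Output directory for report TSVs (`NULL` for none).
#' @param stages Character vector of stages to run, a subset of
#'   `c("call_response", "scan_coevents", "drug_assoc", "lineage",
#'   "cluster")`.
#' @param degree,cap Response-caller parameters.
#' @param k Tuple sizes for drug association (subset of 1:3).
#' @param alpha,fold,min_prevalence,min_count,rounding,correction Engine
#'   parameters (see the respective stage functions).
#' @param seed Seed for the synthetic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(panel = NULL, mutations = NULL,
                            copy_numbers = NULL, lineage = NULL,
                            screens = NULL, out_dir = NULL,
                            stages = c("call_response", "scan_coevents",
                                       "drug_assoc", "lineage", "cluster"),
                            degree = 9L, cap = 0.78, k = c(1L, 2L),
                            alpha = 0.05, fold = 1.5, min_prevalence = 0.12,
                            min_count = 4L,
                            rounding = "rounded", correction = "bh",
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(panel)) {
    for (p in c(mutations, lineage, screens)) {
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("input file not found: %s", p), call. = FALSE)
      }
    }
    if (is.null(mutations) || is.null(screens)) {
      stop("either a panel config or mutation and screen tables are required",
           call. = FALSE)
    }
  }
  structure(list(panel = panel, mutations = mutations,
                 copy_numbers = copy_numbers, lineage = lineage,
                 screens = screens, out_dir = out_dir, stages = stages,
                 degree = degree, cap = cap, k = as.integer(k),
                 alpha = alpha, fold = fold, min_prevalence = min_prevalence,
                 min_count = as.integer(min_count), rounding = rounding,
                 correction = correction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the biomarker-discovery pipeline
#'
#' Executes the configured stages in dependency order and (optionally)
#' writes the report TSVs. Reruns with the same configuration and inputs
#' produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list with the stage results (`matrix`, `screens`, `calls`,
#'   `coevents`, `associations`, `lineage_tests`, `residual`, `tree`) and a
#'   `manifest` recording parameters, seed and per-output row counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(package_version = as.character(utils::packageVersion("coevent")),
                   seed = config$seed,
                   parameters = config[c("degree", "cap", "k", "alpha", "fold",
                                         "min_prevalence", "min_count",
                                         "rounding", "correction")],
                   stages = config$stages, rows = list(), failed = NULL)
  res <- list()
  if (!is.null(config$panel)) {
    panel <- generate_panel(config$panel, out_dir = config$out_dir)
    res$matrix <- panel$matrix
    res$screens <- panel$screens
  } else {
    mut <- load_mutation_table(config$mutations)
    cn <- if (!is.null(config$copy_numbers)) {
      load_copy_number_table(config$copy_numbers)
    }
    lin <- if (!is.null(config$lineage)) load_lineage_table(config$lineage)
    res$matrix <- build_event_matrix(mut, cn, lineage = lin)
    res$screens <- read_screens_tsv(config$screens)
  }

  if ("call_response" %in% config$stages) {
    res$calls <- lapply(res$screens, call_response,
                        degree = config$degree, cap = config$cap)
    manifest$rows$calls <- sum(vapply(res$calls, function(cl)
      length(cl$ordered_cell_lines), integer(1)))
  }
  if ("scan_coevents" %in% config$stages) {
    res$coevents <- population_disequilibrium_scan(
      res$matrix, k = 2L, alpha = config$alpha, rounding = config$rounding,
      correction = config$correction)
    manifest$rows$coevents <- nrow(res$coevents)
  }
  if ("drug_assoc" %in% config$stages) {
    if (is.null(res$calls)) stop("drug_assoc requires call_response", call. = FALSE)
    res$associations <- do.call(rbind, unlist(recursive = FALSE,
      lapply(res$calls, function(cl) {
        if (cl$degenerate) return(NULL)
        lapply(config$k, function(kk) {
          if (kk == 1L) {
            single_event_drug_association(res$matrix, cl,
                                          min_prevalence = config$min_prevalence,
                                          fold = config$fold)
          } else {
            out <- coevent_drug_association(res$matrix, cl, k = kk,
                                            min_count = config$min_count,
                                            fold = config$fold,
                                            alpha = config$alpha,
                                            min_prevalence = config$min_prevalence)
            out[names(empty_assoc_frame())]
          }
        })
      })))
    manifest$rows$associations <-
      if (is.null(res$associations)) 0L else nrow(res$associations)
  }
  if ("lineage" %in% config$stages) {
    if (is.null(res$calls)) stop("lineage requires call_response", call. = FALSE)
    if (is.null(res$matrix$lineage)) {
      manifest$failed <- "lineage: no lineage annotations"
    } else {
      top <- res$associations
      lt <- list(); rs <- list()
      for (cl in res$calls) {
        if (cl$degenerate) next
        cand <- top[top$drug == cl$drug & !is.na(top$p_value) &
                      top$p_value <= config$alpha, , drop = FALSE]
        if (nrow(cand) == 0) next
        loci_list <- strsplit(cand$loci, "::", fixed = TRUE)
        an <- lineage_subtraction_analysis(loci_list, res$matrix, cl,
                                           alpha = config$alpha,
                                           min_prevalence = config$min_prevalence,
                                           fold = config$fold)
        lt[[cl$drug]] <- an$lineage_tests
        rs[[cl$drug]] <- an$residual
      }
      res$lineage_tests <- do.call(rbind, lt)
      res$residual <- do.call(rbind, rs)
      manifest$rows$lineage_tests <-
        if (is.null(res$lineage_tests)) 0L else nrow(res$lineage_tests)
    }
  }
  if ("cluster" %in% config$stages) {
    gi <- gi_matrix_from_screens(res$screens)
    scaled <- scale_profiles(gi)
    res$scaled <- scaled
    res$tree <- tryCatch(hierarchical_cluster(scaled, axis = "drugs"),
                         error = function(e) NULL)
  }
  if (!is.null(config$out_dir)) {
    write_reports(res, config$out_dir)
  }
  res$manifest <- manifest
  res
}

#' Write pipeline report tables
#'
#' Writes `calls.tsv`, `coevents.tsv`, `drug_assoc.tsv`,
#' `lineage_assoc.tsv` and `residual_assoc.tsv` (those present in
#' `results`). Floating-point values are rendered with 9 decimal places and
#' the infinite S/R sentinel as literal `inf`, so every row can be
#' recomputed from its own printed counts.
#'
#' @param results Stage results from [run_pipeline()] (any subset).
#' @param out_dir Output directory; must be writable (checked before any
#'   file is written).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) {
    stop(sprintf("output directory not writable: %s", out_dir), call. = FALSE)
  }
  written <- character(0)
  emit <- function(tab, name) {
    path <- file.path(out_dir, name)
    num <- vapply(tab, is.double, logical(1))
    for (j in which(num)) tab[[j]] <- format_gi_number(tab[[j]])
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  if (!is.null(results$calls)) emit(calls_table(results$calls), "calls.tsv")
  if (!is.null(results$coevents)) emit(results$coevents, "coevents.tsv")
  if (!is.null(results$associations)) {
    emit(results$associations, "drug_assoc.tsv")
  }
  if (!is.null(results$lineage_tests)) {
    emit(results$lineage_tests, "lineage_assoc.tsv")
  }
  if (!is.null(results$residual)) emit(results$residual, "residual_assoc.tsv")
  invisible(written)
}

# 9-decimal rendering with the "inf" sentinel for infinite S/R ratios.
format_gi_number <- function(x) {
  out <- ifelse(is.na(x), "NA",
                ifelse(is.infinite(x), "inf", sprintf("%.9f", x)))
  out
}
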