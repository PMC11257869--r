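# End-to-end orchestration: validate a workbook, run the requested
# analyses (base case, frontier, subgroups, DSA, thresholds, PSA), write
# CSV artifacts plus a JSON summary, and record a hash-stable manifest.

.ANALYSES <- c("basecase", "frontier", "subgroups", "dsa", "thresholds", "psa")

#' Run the full analysis pipeline
#'
#' Executes the requested analyses on a workbook and writes one CSV per
#' artifact, a JSON summary, a plain-text log (seed, package version,
#' curve-clamping counts) and a manifest with an MD5 hash per file.
#' Deterministic for a fixed seed: identical calls produce hash-identical
#' artifacts.
#'
#' @param wb a `cea_workbook` (e.g. [demo_workbook()]) or path to a YAML
#'   workbook
#' @param out_dir output directory (created if needed)
#' @param analyses subset of `"basecase"`, `"frontier"`, `"subgroups"`,
#'   `"dsa"`, `"thresholds"`, `"psa"`
#' @param seed RNG seed for the stochastic analyses
#' @param psa_draws Monte Carlo draws for the PSA (default 10,000)
#' @param dsa_strategy intervention for DSA/threshold analyses (default:
#'   the non-reference strategy with the highest base-case QALYs)
#' @param subgroup_hrs optional subgroup HR table for [subgroup_run()]
#' @param wtp_grid WTP grid for the acceptability curves
#' @return invisibly, the manifest data.frame (file, md5)
#' @export
run_pipeline <- function(wb, out_dir, analyses = c("basecase", "frontier"),
                         seed = 1L, psa_draws = 10000,
                         dsa_strategy = NULL, subgroup_hrs = NULL,
                         wtp_grid = seq(0, 60000, by = 500)) {
  if (is.character(wb)) wb <- read_workbook(wb)
  validate_workbook(wb)
  bad <- setdiff(analyses, .ANALYSES)
  if (length(bad)) {
    stop("unknown analyses: ", paste(bad, collapse = ", "),
         " (choose from ", paste(.ANALYSES, collapse = ", "), ")")
  }
  if (length(analyses) == 0) stop("no analyses requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("sclccea %s", as.character(utils::packageVersion("sclccea"))),
                 sprintf("seed: %d", seed),
                 sprintf("analyses: %s", paste(analyses, collapse = ", ")))
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "")
    written <<- c(written, path)
    path
  }
  summary <- list(seed = seed)

  base <- run_base_case(wb)
  base_tab <- ce_table(base)
  if (is.null(dsa_strategy)) {
    cand <- base_tab[base_tab$strategy != "chemotherapy", ]
    dsa_strategy <- cand$strategy[which.max(cand$qalys)]
  }

  if ("basecase" %in% analyses) {
    emit(base_tab, "basecase.csv")
    summary$basecase <- base_tab
  }
  if ("frontier" %in% analyses) {
    fr <- frontier(base)
    emit(fr$table, "frontier.csv")
    write_stepwise(fr, file.path(out_dir, "stepwise.csv"))
    written <- c(written, file.path(out_dir, "stepwise.csv"))
    summary$frontier <- fr$table[, c("strategy", "status", "seq_icer")]
  }
  if ("subgroups" %in% analyses) {
    if (is.null(subgroup_hrs)) {
      log_lines <- c(log_lines, "subgroups requested but no HR table; skipped")
    } else {
      sg <- subgroup_run(wb, subgroup_hrs)
      sg_tab <- do.call(rbind, lapply(names(sg), function(s) {
        cbind(subgroup = s, sg[[s]]$table)
      }))
      emit(sg_tab, "subgroups.csv")
    }
  }
  specs <- default_dsa_specs(wb, dsa_strategy)
  if ("dsa" %in% analyses) {
    runner <- make_icer_runner(wb, dsa_strategy)
    tor <- dsa_oneway(specs, runner)
    emit(tor, "tornado.csv")
    summary$dsa_top <- tor$param[1]
  }
  if ("thresholds" %in% analyses) {
    runner <- make_icer_runner(wb, dsa_strategy)
    th <- lapply(specs, function(sp) {
      v <- tryCatch(threshold_search(sp, wb$settings$wtp_high, runner),
                    error = function(e) NA_real_)
      data.frame(param = sp$name, wtp = wb$settings$wtp_high, threshold = v)
    })
    emit(do.call(rbind, c(th, list(make.row.names = FALSE))), "thresholds.csv")
  }
  if ("psa" %in% analyses) {
    ps <- psa(specs, make_ce_runner(wb), n = psa_draws, seed = seed)
    emit(ps$samples, "psa_samples.csv")
    cc <- ceac(ps, wtp_grid)
    emit(cc, "ceac.csv")
    summary$psa_draws <- psa_draws
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  written <- c(written, file.path(out_dir, "summary.json"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  written <- c(written, file.path(out_dir, "run.log"))

  manifest <- data.frame(file = basename(written),
                         md5 = as.character(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
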