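#' Run the full ancestry-estimation pipeline
#'
#' read -> impute missing -> MAF filter -> center + SVD -> archetypal
#' analysis on the scores -> write outputs. Produces the `.Q`-style ancestry
#' fractions (`<out>.alpha.Q` plus `<out>.alpha.Q.samples`), the archetype
#' weights (`<out>.beta.txt`), the K x M SNP-space archetypes
#' (`<out>.archetypes.txt`), a JSON run report (`<out>.report.json`), and
#' optionally the compositional and bar plots as PDFs.
#'
#' @param input path to the genotype input.
#' @param out output prefix (files are written as `<out>.*`).
#' @param k number of archetypes.
#' @param format `"vcf"` or `"matrix"`.
#' @param C,tol,max_iter,init,seed,restarts solver settings, see
#'   [aa_config()].
#' @param maf_threshold minor-allele-frequency cut; variants with MAF
#'   strictly below it are removed. Default 0.1.
#' @param n_components optional number of leading SVD components to retain;
#'   default all (N - 1).
#' @param labels optional path to a two-column sample/population file.
#' @param plots logical; write the compositional and bar plots.
#' @param verbose logical; log stages to stderr.
#' @return invisibly, a list with the `aa_fit`, the projection, the filtered
#'   panel and the output paths.
#' @export
run_pipeline <- function(input, out, k, format = c("vcf", "matrix"),
                         C = 0.001, tol = 0.001, max_iter = 50L,
                         init = "furthest_sum", seed = 1L, restarts = 1L,
                         maf_threshold = 0.1, n_components = NULL,
                         labels = NULL, plots = FALSE, verbose = TRUE) {
  format <- match.arg(format)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) say("[aamix] %s (t=%.1fs)", what,
                              proc.time()[["elapsed"]] - t0)

  g <- if (format == "vcf") read_vcf(input) else read_dosage_matrix(input)
  stage(sprintf("read %d samples x %d variants from %s",
                nrow(g$dosages), ncol(g$dosages), input))
  if (!is.null(labels)) {
    lab <- read_labels(labels)
    g$populations <- unname(lab[g$sample_ids])
  }
  g <- impute_missing(g)
  g <- filter_rare_variants(g, maf_threshold)
  stage(sprintf("after MAF >= %g filter: %d variants", maf_threshold,
                ncol(g$dosages)))

  pm <- fit_projection(g)
  if (!is.null(n_components)) pm <- truncate_projection(pm, n_components)
  stage(sprintf("SVD: retained %d components", length(pm$sigma)))

  fit <- archetypal_analysis(pm$scores, config = aa_config(
    k = k, C = C, tol = tol, max_iter = max_iter, init = init,
    seed = seed, restarts = restarts))
  stage(sprintf("AA fit: K=%d, RSS=%.6g, EV=%.4f, %d iteration(s)%s",
                k, fit$rss, fit$explained_variance, fit$n_iter,
                if (fit$converged) "" else " (max_iter reached)"))

  arch_snp <- archetypes_in_snp_space(g, fit$beta)
  paths <- list(alpha = paste0(out, ".alpha.Q"),
                beta = paste0(out, ".beta.txt"),
                archetypes = paste0(out, ".archetypes.txt"),
                report = paste0(out, ".report.json"))
  write_fractions(fit$alpha, paths$alpha, sample_ids = g$sample_ids)
  write_archetypes(t(fit$beta), paths$beta)
  write_archetypes(arch_snp, paths$archetypes)
  report <- list(
    input = input, format = format,
    n_samples = nrow(g$dosages), n_variants = ncol(g$dosages),
    config = unclass(fit$config), n_components = length(pm$sigma),
    maf_threshold = maf_threshold,
    n_iter = fit$n_iter, converged = fit$converged,
    rss_trace = fit$rss_trace, rss = fit$rss,
    explained_variance = fit$explained_variance,
    free_parameters = fit$df
  )
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (plots && k >= 2) {
    paths$composition <- paste0(out, ".composition.pdf")
    paths$bars <- paste0(out, ".bars.pdf")
    compositional_plot(fit$alpha, g$populations, out = paths$composition)
    ancestry_barplot(fit$alpha, g$populations, out = paths$bars)
  }
  stage("wrote outputs")
  invisible(list(fit = fit, projection = pm, panel = g, paths = paths))
}

#' Command-line entry point
#'
#' Thin argv-level wrapper over [run_pipeline()] used by the installed
#' `aamix.R` script (`system.file("cli", "aamix.R", package = "aamix")`).
#' Returns instead of exiting so it is testable: 0 on success, 2 on a usage
#' error, 1 on a runtime failure.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--format", type = "character", default = "vcf",
                          help = "vcf or matrix [default %default]"),
    optparse::make_option("--k", type = "integer"),
    optparse::make_option("--C", type = "double", default = 0.001),
    optparse::make_option("--tol", type = "double", default = 0.001),
    optparse::make_option("--max-iter", type = "integer", default = 50L,
                          dest = "max_iter"),
    optparse::make_option("--init", type = "character",
                          default = "furthest_sum"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--restarts", type = "integer", default = 1L),
    optparse::make_option("--maf", type = "double", default = 0.1),
    optparse::make_option("--n-components", type = "integer", default = NULL,
                          dest = "n_components"),
    optparse::make_option("--labels", type = "character", default = NULL),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--plots", action = "store_true", default = FALSE),
    optparse::make_option("--verbose", action = "store_true", default = TRUE),
    optparse::make_option("--quiet", action = "store_false", default = TRUE,
                          dest = "verbose")
  )
  parser <- optparse::OptionParser(option_list = spec, prog = "aamix")
  opt <- tryCatch(
    optparse::parse_args(parser, args = argv),
    error = function(e) e, warning = function(w) w
  )
  usage_fail <- function(msg) {
    message("usage error: ", msg)
    2L
  }
  if (inherits(opt, "condition")) return(usage_fail(conditionMessage(opt)))
  if (is.null(opt$input)) return(usage_fail("--input is required"))
  if (is.null(opt$out)) return(usage_fail("--out is required"))
  if (is.null(opt$k) || is.na(opt$k) || opt$k < 1) {
    return(usage_fail("--k must be a positive integer"))
  }
  if (!opt$format %in% c("vcf", "matrix")) {
    return(usage_fail("--format must be 'vcf' or 'matrix'"))
  }
  if (!opt$init %in% c("furthest_sum", "random_uniform", "random_sample")) {
    return(usage_fail("--init must be furthest_sum, random_uniform or random_sample"))
  }
  if (!file.exists(opt$input)) return(usage_fail("input not readable: " %+% opt$input))
  res <- tryCatch({
    run_pipeline(input = opt$input, out = opt$out, k = opt$k,
                 format = opt$format, C = opt$C, tol = opt$tol,
                 max_iter = opt$max_iter, init = opt$init, seed = opt$seed,
                 restarts = opt$restarts, maf_threshold = opt$maf,
                 n_components = opt$n_components, labels = opt$labels,
                 plots = opt$plots, verbose = opt$verbose)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  res
}

`%+%` <- function(a, b) paste0(a, b)
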