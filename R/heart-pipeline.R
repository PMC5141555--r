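.CLEVELAND_COLS <- c("age", "sex", "cp", "trestbps", "chol", "fbs",
                     "restecg", "thalach", "exang", "oldpeak", "slope",
                     "ca", "thal", "num")

#' Read a Cleveland-format heart-disease file
#'
#' Parses the classical comma-delimited 14-column layout (age, sex, cp,
#' trestbps, chol, fbs, restecg, thalach, exang, oldpeak, slope, ca, thal,
#' num) with `?` marking missing cells.  A header row is auto-detected.
#' Rows with the wrong field count or non-numeric, non-`?` tokens raise
#' errors naming the offending line.
#'
#' @param path file path.
#' @return data frame with the 14 canonical columns (`NA` for `?`);
#'   attribute `missing_census` counts missing cells per column.
#' @export
read_cleveland <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, sprintf("empty file: %s", path),
          class = "poismix_format")
  toks <- strsplit(lines, ",", fixed = TRUE)
  first <- trimws(toks[[1L]])
  is_header <- all(suppressWarnings(is.na(as.numeric(first))) & first != "?")
  if (is_header) {
    toks <- toks[-1L]
    .assert(length(toks) > 0, sprintf("no data rows in %s", path),
            class = "poismix_format")
  }
  nf <- lengths(toks)
  if (any(nf != 14L)) {
    bad <- which(nf != 14L)[1L]
    .assert(FALSE, sprintf(
      "line %d has %d fields, expected 14", bad + is_header, nf[bad]),
      class = "poismix_format")
  }
  M <- matrix(trimws(unlist(toks)), ncol = 14L, byrow = TRUE)
  vals <- suppressWarnings(as.numeric(M))
  bad <- is.na(vals) & M != "?"
  if (any(bad)) {
    cell <- which(matrix(bad, ncol = 14L), arr.ind = TRUE)[1L, ]
    .assert(FALSE, sprintf(
      "line %d, column %s: cannot parse token '%s'",
      cell[1L] + is_header, .CLEVELAND_COLS[cell[2L]],
      M[cell[1L], cell[2L]]), class = "poismix_parse")
  }
  out <- as.data.frame(matrix(vals, ncol = 14L,
                              dimnames = list(NULL, .CLEVELAND_COLS)))
  attr(out, "missing_census") <- colSums(is.na(out))
  out
}

#' Write a dataset in the Cleveland 14-column layout
#'
#' Serializes a simulated (or real) dataset as comma-delimited text with a
#' header row, covariates first and the count response `num` last, at full
#' double precision so a write/read cycle reproduces the values exactly.
#'
#' @param data a [count_dataset()] whose `X` carries 13 covariates.
#' @param path output file path.
#' @export
write_count_data <- function(data, path) {
  covs <- data$X[, -1L, drop = FALSE]
  tab <- cbind(covs, num = data$y)
  chr <- apply(tab, 2L, function(col) sprintf("%.17g", col))
  writeLines(c(paste(colnames(tab), collapse = ","),
               apply(chr, 1L, paste, collapse = ",")), path)
  invisible(path)
}

#' Preprocess a parsed Cleveland table into a modelling dataset
#'
#' Default policy is complete-case deletion: rows with any missing cell are
#' dropped (and logged).  The response is `num`; the component block is the
#' intercept plus all 13 covariates numerically coded (categorical
#' attributes enter as integer scores, one coefficient each); the gate block
#' defaults to the same covariates.
#'
#' @param raw data frame from [read_cleveland()].
#' @param policy `"complete_case"` (drop) or `"keep"` (errors if missing
#'   cells are present, since no imputation is provided).
#' @param gate_covariates optional character subset of covariates for the
#'   gate block `W`; default all 13 (`W = X`).
#' @return a [count_dataset()]; attribute `preprocess_log` records row
#'   counts and dropped rows.
#' @export
preprocess <- function(raw, policy = c("complete_case", "keep"),
                       gate_covariates = NULL) {
  policy <- match.arg(policy)
  covs <- setdiff(.CLEVELAND_COLS, "num")
  .assert(all(c(covs, "num") %in% names(raw)),
          "table lacks the canonical 14 columns")
  if (policy == "keep") {
    .assert(!anyNA(raw), "missing cells present and no imputation available")
  }
  cc <- complete.cases(raw)
  used <- raw[cc, , drop = FALSE]
  .assert(nrow(used) > 0, "no complete rows survive preprocessing")
  X <- as.matrix(used[covs])
  W <- if (is.null(gate_covariates)) NULL else {
    .assert(all(gate_covariates %in% covs), "unknown gate covariate")
    as.matrix(used[gate_covariates])
  }
  out <- count_dataset(used$num, X, W, row_ids = which(cc))
  attr(out, "preprocess_log") <- list(
    n_parsed = nrow(raw), n_used = nrow(used), dropped_rows = which(!cc))
  out
}

#' Posterior-probability rootogram data
#'
#' Histograms of the posterior membership probabilities per component over
#' fixed bins on [0, 1] — the standard mixture separation diagnostic
#' (U-shaped mass means well-separated clusters).  Observations with
#' posterior below `omit_below` in a component are omitted from that
#' component's histogram, the usual plotting convention.  A separation score
#' (fraction of observations whose largest posterior exceeds 0.8) is
#' attached.
#'
#' @param model fitted `poismix` model.
#' @param data a [count_dataset()].
#' @param bins number of bins (default 20).
#' @param omit_below omission threshold (default 0.01; set 0 to keep all).
#' @return object of class `rootogram_data`: `breaks`, `counts`
#'   (bins x categories), `retained` per category, `separation_score`.
#' @export
rootogram <- function(model, data, bins = 20L, omit_below = 0.01) {
  tau <- e_step(data, model)$tau
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- apply(tau, 2L, function(tk) {
    tk <- tk[tk >= omit_below]
    tabulate(pmin(findInterval(tk, breaks, rightmost.closed = TRUE), bins),
             bins)
  })
  colnames(counts) <- .category_names(model)
  structure(list(breaks = breaks, counts = counts,
                 retained = colSums(counts),
                 separation_score = mean(apply(tau, 1L, max) > 0.8),
                 omit_below = omit_below),
            class = "rootogram_data")
}

#' @export
print.rootogram_data <- function(x, ...) {
  cat(sprintf("rootogram: %d bins, separation score %.3f\n",
              length(x$breaks) - 1L, x$separation_score))
  cat("retained per component:",
      paste(sprintf("%s=%d", colnames(x$counts), x$retained),
            collapse = ", "), "\n")
  invisible(x)
}

#' Run the full heart-disease modelling pipeline
#'
#' End-to-end analysis of a Cleveland-format file (or an in-memory
#' [count_dataset()]): dispersion diagnostic, then BIC scans over four model
#' classes — the no-covariate Poisson mixture, the standard (fixed-weight)
#' mixture regression, the concomitant-variable mixture regression, and the
#' zero-inflated concomitant model — followed by classification, rate-ratio
#' tables, rootograms and (optionally) bootstrap confidence intervals for
#' the BIC-chosen concomitant and zero-inflated models.  Any stage failure
#' is recorded in `$errors` and the report still returned.
#'
#' @param input path to a Cleveland-format file, or a [count_dataset()].
#' @param K_range candidate component counts (default 1:4).
#' @param seed master seed driving every stage.
#' @param config a [fit_config()]; default uses `seed`.
#' @param boot_B bootstrap replicates for the chosen models (0 disables;
#'   minimum 50 otherwise).
#' @param bins rootogram bins.
#' @param gate_covariates optional gate covariate subset (file input only).
#' @param out_dir optional directory; when given, the report is serialized
#'   as JSON plus delimited tables.
#' @return object of class `analysis_report`.
#' @export
run_analysis <- function(input, K_range = 1:4, seed = 1L,
                         config = fit_config(seed = seed), boot_B = 0L,
                         bins = 20L, gate_covariates = NULL, out_dir = NULL) {
  report <- list(errors = list(),
                 provenance = list(seed = seed,
                                   K_range = as.integer(K_range),
                                   n_restarts = config$n_restarts,
                                   tol = config$tol, boot_B = boot_B))
  record <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[stage]] <<- conditionMessage(e)
      NULL
    })
  }
  if (is.character(input)) {
    raw <- read_cleveland(input)
    data <- preprocess(raw, gate_covariates = gate_covariates)
    report$provenance$input <- input
    report$provenance$file_md5 <- unname(tools::md5sum(input))
    report$provenance$missing_census <- attr(raw, "missing_census")
    report$preprocess <- attr(data, "preprocess_log")
  } else {
    .assert(inherits(input, "count_dataset"), "input must be a path or dataset")
    data <- input
  }
  report$n <- length(data$y)
  report$dispersion <- record("dispersion", dispersion_check(data))
  report$scans <- list(
    no_covariate = record("scan_no_covariate",
      scan_components(data, K_range, mode = "fixed", config = config,
                      intercept_only = TRUE)),
    standard = record("scan_standard",
      scan_components(data, K_range, mode = "fixed", config = config)),
    concomitant = record("scan_concomitant",
      scan_components(data, K_range, mode = "concomitant", config = config))
  )
  if (any(data$y == 0)) {
    report$scans$zip <- record("scan_zip",
      scan_components(data, K_range, mode = "concomitant", config = config,
                      zero_inflated = TRUE))
  }
  report$chosen <- list()
  for (nm in names(report$scans)) {
    tab <- report$scans[[nm]]
    if (is.null(tab)) next
    m <- best_model(tab)
    sdat <- attr(tab, "data")   # matches the design the model was fitted on
    cls <- posterior_classify(m, sdat)
    entry <- list(
      model = m, tag = attr(tab, "best_by_bic"), K = m$K,
      sizes = cls$sizes, priors = cls$priors,
      rate_ratios = rate_ratios(m, gate = TRUE),
      rootogram = rootogram(m, sdat, bins = bins)
    )
    if (boot_B >= 50 && nm %in% c("concomitant", "zip")) {
      entry$ci <- record(paste0("boot_", nm),
        bootstrap_confidence_intervals(sdat, m, B = boot_B, config = config))
    }
    report$chosen[[nm]] <- entry
  }
  report$comparison <- do.call(rbind, lapply(names(report$scans), function(nm) {
    tab <- report$scans[[nm]]
    if (is.null(tab)) return(NULL)
    best <- tab[tab$model_tag == attr(tab, "best_by_bic"), , drop = FALSE]
    cbind(class = nm, best)
  }))
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== poismix analysis report ==\n")
  cat(sprintf("n = %d observations\n", x$n))
  if (!is.null(x$preprocess)) {
    cat(sprintf("parsed %d rows, used %d after complete-case deletion\n",
                x$preprocess$n_parsed, x$preprocess$n_used))
  }
  d <- x$dispersion
  if (!is.null(d)) {
    cat(sprintf("dispersion: mean %.3f, var %.3f, ratio %.3f (%s-dispersed)\n",
                d$mean, d$variance, d$ratio, d$verdict))
  }
  cat("\nBest model per class (by BIC):\n")
  if (!is.null(x$comparison)) print(x$comparison, row.names = FALSE)
  for (nm in names(x$chosen)) {
    ch <- x$chosen[[nm]]
    cat(sprintf("\n[%s] %s: sizes %s, priors %s, separation %.3f\n",
                nm, ch$tag, paste(ch$sizes, collapse = "/"),
                paste(round(ch$priors, 3), collapse = "/"),
                ch$rootogram$separation_score))
  }
  if (length(x$errors)) {
    cat("\nstage failures:\n")
    for (nm in names(x$errors)) cat(sprintf("  %s: %s\n", nm, x$errors[[nm]]))
  }
  invisible(x)
}

# serialize the report: JSON tree plus delimited tables per scan/CI
.write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ser <- list(
    n = report$n, provenance = report$provenance,
    preprocess = report$preprocess, dispersion = report$dispersion,
    comparison = report$comparison,
    scans = lapply(report$scans, as.data.frame),
    chosen = lapply(report$chosen, function(ch) list(
      tag = ch$tag, K = ch$K, sizes = as.list(ch$sizes),
      priors = as.list(ch$priors),
      rate_ratios = ch$rate_ratios$rates,
      gate_ratios = ch$rate_ratios$gate,
      separation_score = ch$rootogram$separation_score,
      rootogram_counts = as.data.frame(ch$rootogram$counts),
      ci = ch$ci
    )),
    errors = report$errors
  )
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(report$scans)) {
    write.csv(as.data.frame(report$scans[[nm]]),
              file.path(out_dir, paste0("scan_", nm, ".csv")),
              row.names = FALSE)
  }
  for (nm in names(report$chosen)) {
    ci <- report$chosen[[nm]]$ci
    if (!is.null(ci)) {
      write.csv(ci, file.path(out_dir, paste0("ci_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  invisible(out_dir)
}
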