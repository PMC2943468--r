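#' Read a qPCR Ct table
#'
#' Reads a CSV of raw threshold-cycle values with columns `sample_id`,
#' `gene`, `ct`, `replicate` and optionally `group`. Ct values must be
#' finite and positive (typical assays report 10-40 cycles).
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(tab)
}

validate_ct_table <- function(tab) {
  required <- c("sample_id", "gene", "ct", "replicate")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("Ct table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(tab$ct) || any(!is.finite(tab$ct)) || any(tab$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  tab
}

#' Delta-Ct of a sample
#'
#' Mean target Ct minus mean reference (housekeeping) Ct, with replicates
#' aggregated by the mean before differencing.
#'
#' @param target_cts Numeric vector of target-gene Ct replicates.
#' @param reference_cts Numeric vector of reference-gene Ct replicates.
#' @return Single number, cycles.
#' @export
delta_ct <- function(target_cts, reference_cts) {
  if (length(target_cts) == 0L || length(reference_cts) == 0L) {
    stop("need at least one replicate for target and reference")
  }
  if (any(!is.finite(target_cts)) || any(!is.finite(reference_cts))) {
    stop("Ct values must be finite")
  }
  mean(target_cts) - mean(reference_cts)
}

#' Relative expression by the comparative-Ct method
#'
#' `2^(-(sample_dct - calibrator_dct))`: the fold change of the target gene
#' in a sample relative to the calibrator, assuming perfect doubling per
#' cycle (amplification efficiency 2, no efficiency correction).
#'
#' @param sample_dct Sample delta-Ct (cycles).
#' @param calibrator_dct Calibrator delta-Ct (cycles).
#' @return Unitless fold change (> 0).
#' @export
relative_expression <- function(sample_dct, calibrator_dct) {
  if (any(!is.finite(sample_dct)) || any(!is.finite(calibrator_dct))) {
    stop("delta-Ct values must be finite")
  }
  2^(-(sample_dct - calibrator_dct))
}

#' Per-sample and per-group relative expression from a Ct table
#'
#' Computes each sample's delta-Ct (target minus reference, replicate means),
#' sets the calibrator delta-Ct to the mean delta-Ct of the designated
#' calibrator group, and reports `2^(-delta_delta_ct)` per sample plus group
#' mean +/- SEM. Results are invariant to adding a constant number of cycles
#' to every Ct.
#'
#' @param records Data.frame with columns `sample_id`, `gene`, `ct`,
#'   `replicate`, `group`.
#' @param target Target gene label (e.g. `"VCAM1"`).
#' @param reference Housekeeping gene label (e.g. `"GAPDH"`).
#' @param calibrator_group Group whose mean delta-Ct defines fold = 1.
#' @return An object of class `expression_result`: `per_sample` (data.frame
#'   sample_id, group, delta_ct, delta_delta_ct, rel_expression) and
#'   `per_group` (data.frame group, n, mean_rel_expression, sem).
#' @export
group_expression <- function(records, target, reference, calibrator_group) {
  records <- validate_ct_table(records)
  if (!"group" %in% names(records)) {
    stop("records must contain a 'group' column for group-relative reporting")
  }
  samples <- unique(records[, c("sample_id", "group")])
  if (!calibrator_group %in% samples$group) {
    stop("calibrator group '", calibrator_group, "' not present")
  }
  dct <- vapply(seq_len(nrow(samples)), function(i) {
    sid <- samples$sample_id[i]
    tc <- records$ct[records$sample_id == sid & records$gene == target]
    rc <- records$ct[records$sample_id == sid & records$gene == reference]
    if (length(tc) == 0L) stop("sample '", sid, "' has no ", target, " Ct")
    if (length(rc) == 0L) {
      stop("sample '", sid, "' is missing the reference gene ", reference)
    }
    delta_ct(tc, rc)
  }, numeric(1))
  calibrator_dct <- mean(dct[samples$group == calibrator_group])
  ddct <- dct - calibrator_dct
  per_sample <- data.frame(
    sample_id = samples$sample_id, group = samples$group,
    delta_ct = dct, delta_delta_ct = ddct,
    rel_expression = 2^(-ddct)
  )
  per_group <- do.call(rbind, lapply(split(per_sample, per_sample$group),
                                     function(s) {
    data.frame(
      group = s$group[1], n = nrow(s),
      mean_rel_expression = mean(s$rel_expression),
      sem = if (nrow(s) > 1) {
        stats::sd(s$rel_expression) / sqrt(nrow(s))
      } else 0
    )
  }))
  rownames(per_group) <- NULL
  structure(list(per_sample = per_sample, per_group = per_group,
                 target = target, reference = reference,
                 calibrator_group = calibrator_group),
            class = "expression_result")
}

#' @export
print.expression_result <- function(x, ...) {
  cat(sprintf("expression_result: %s relative to %s, calibrator '%s'\n",
              x$target, x$reference, x$calibrator_group))
  print(x$per_group)
  invisible(x)
}

#' Encode fold changes as a synthetic Ct table
#'
#' Inverts the comparative-Ct map: builds a Ct table in which each sample's
#' relative expression (versus a single-sample calibrator group) decodes to
#' the requested fold change exactly. Used to construct round-trip checks
#' and worked examples; reference Cts are constant at `reference_ct`, target
#' Cts are `reference_ct + base_dct - log2(fold)`.
#'
#' @param folds Named numeric vector of fold changes, one per sample; names
#'   become sample ids. Must include a sample named `"calibrator"` or one is
#'   added with fold 1.
#' @param groups Optional character vector of group labels (same length and
#'   order as `folds` after calibrator addition); defaults to the sample
#'   names.
#' @param reference_ct Constant housekeeping Ct (default 20).
#' @param base_dct Calibrator delta-Ct (default 8).
#' @param replicates Number of identical replicates per gene (default 2).
#' @return A Ct table data.frame suitable for [group_expression()].
#' @export
encode_fold_table <- function(folds, groups = NULL, reference_ct = 20,
                              base_dct = 8, replicates = 2L) {
  if (is.null(names(folds))) {
    names(folds) <- paste0("s", seq_along(folds))
  }
  if (!"calibrator" %in% names(folds)) {
    folds <- c(folds, calibrator = 1)
  }
  if (any(folds <= 0)) stop("fold changes must be positive")
  if (is.null(groups)) {
    groups <- names(folds)
    groups[names(folds) == "calibrator"] <- "calibrator"
  }
  if (length(groups) != length(folds)) {
    stop("groups must match folds in length")
  }
  rows <- lapply(seq_along(folds), function(i) {
    target_ct <- reference_ct + base_dct - log2(folds[i])
    data.frame(
      sample_id = rep(names(folds)[i], 2L * replicates),
      gene = rep(c("target", "reference"), each = replicates),
      ct = rep(c(target_ct, reference_ct), each = replicates),
      replicate = rep(seq_len(replicates), 2L),
      group = rep(groups[i], 2L * replicates)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write expression results as CSV
#'
#' @param result A [group_expression()] result.
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Named character vector of written paths, invisibly.
#' @export
write_expression <- function(result, dir, prefix = "expression") {
  stopifnot(inherits(result, "expression_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, paste0(prefix, "_per_sample.csv"))
  p2 <- file.path(dir, paste0(prefix, "_per_group.csv"))
  utils::write.csv(result$per_sample, p1, row.names = FALSE)
  utils::write.csv(result$per_group, p2, row.names = FALSE)
  invisible(c(per_sample = p1, per_group = p2))
}
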