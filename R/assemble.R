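# Assembly of the adult log10-wingspan trait vector: two-stage missing-data
# estimation (terminal wing phalanx first, then wingspan itself) by
# phylogenetic GLS, with standard errors carried into downstream model
# fitting as per-tip measurement error.

#' Keep only adult taxa
#'
#' @param table measurement table with a `status` column.
#' @return the adult subset; errors if none remain.
#' @export
filter_adults <- function(table) {
  if (!"status" %in% names(table)) stop_fmt("no 'status' column")
  out <- table[table$status == "adult", , drop = FALSE]
  if (!nrow(out)) stop_fmt("no adult taxa remain; analysis cannot proceed")
  message(sprintf("filter_adults: %d of %d taxa retained", nrow(out), nrow(table)))
  out
}

#' Compute a wingspan from complete wing elements
#'
#' The wingspan is the summed length of the configured forelimb elements of
#' one wing (humerus + ulna + metacarpal IV + wing-finger phalanges 1-4, in
#' mm), multiplied by the taxon's `rescale_factor`, converted to metres and
#' log10-transformed.
#'
#' @param record one-row measurement table (or a list with the element
#'   fields and `rescale_factor`).
#' @param elements character vector of summed element columns.
#' @return log10 wingspan in metres, or `NA` if any element is missing.
#' @export
#' @examples
#' rec <- list(humerus = 100, ulna = 200, mcIV = 150, phIV1 = 250,
#'             phIV2 = 220, phIV3 = 180, phIV4 = 60, rescale_factor = 1)
#' compute_wingspan(rec) # log10(1.160) ~ 0.0645
compute_wingspan <- function(record, elements = wingspan_elements()) {
  vals <- vapply(elements, function(el) {
    v <- record[[el]]
    if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v)
  }, 0)
  if (anyNA(vals)) return(NA_real_)
  rf <- record[["rescale_factor"]] %||% 1
  if (is.na(rf)) rf <- 1
  log10(sum(vals) * rf / 1000)
}

#' Estimate missing terminal wing phalanges (phalanx IV-4)
#'
#' Fits a phylogenetic (`lambda = 1`) regression of log10 phalanx IV-4
#' length on log10 phalanx IV-3 length over taxa with both, then fills taxa
#' missing IV-4 but possessing IV-3. Filled values carry the fit's
#' prediction standard error (sd of predicted-minus-known on the training
#' taxa, log10 mm) in the `phIV4_se_log10` column; observed values are
#' never altered, and the operation is idempotent.
#'
#' @param table measurement table.
#' @param tree calibrated `phylo` covering (at least some of) the taxa.
#' @param exclude taxa excluded from regression fitting only (outliers);
#'   their own values are kept and can still be imputed.
#' @param lambda_mode lambda treatment for the regression (default fixed 1).
#' @return the table with IV-4 filled where possible, plus logical column
#'   `phIV4_imputed` and numeric `phIV4_se_log10`.
#' @export
estimate_phalanx4 <- function(table, tree, exclude = character(),
                              lambda_mode = "fixed1") {
  if (!"phIV4_imputed" %in% names(table)) {
    table$phIV4_imputed <- FALSE
    table$phIV4_se_log10 <- 0
  }
  train <- !is.na(table$phIV4) & !is.na(table$phIV3) & !table$phIV4_imputed &
    !(table$taxon %in% exclude) & table$taxon %in% tree$tip.label
  if (sum(train) < 3L) stop_fmt("too few taxa with both phalanges to fit (%d)", sum(train))
  x <- stats::setNames(log10(table$phIV3[train]), table$taxon[train])
  y <- stats::setNames(log10(table$phIV4[train]), table$taxon[train])
  fit <- pgls_fit(x, y, tree, lambda_mode)
  pred_known <- predict(fit, x[fit$taxa])
  pse <- stats::sd(pred_known - y[fit$taxa])
  fill <- is.na(table$phIV4) & !is.na(table$phIV3)
  if (any(fill)) {
    table$phIV4[fill] <- 10^predict(fit, log10(table$phIV3[fill]))
    table$phIV4_imputed[fill] <- TRUE
    table$phIV4_se_log10[fill] <- pse
  }
  n_skip <- sum(is.na(table$phIV4) & is.na(table$phIV3))
  if (n_skip) message(sprintf("estimate_phalanx4: %d taxa lack phalanx IV-3; left unchanged", n_skip))
  attr(table, "phIV4_fit") <- fit
  table
}

#' Assemble the wingspan trait vector with a predictor cascade
#'
#' Directly computable wingspans (all configured wing elements present,
#' possibly after phalanx IV-4 imputation) are used preferentially with
#' `se = 0` (or the delta-method propagation of the IV-4 prediction error
#' where IV-4 was imputed). For the remaining taxa, per-element regressions
#' of log10 wingspan on log10 element length are fitted on the direct
#' subset -- lambda chosen per predictor by the AICc protocol of
#' [select_predictor()] -- and the first available predictor in `order`
#' supplies the estimate, with that predictor's mean standard estimate
#' error as `se`. Taxa with no usable predictor are excluded with a logged
#' reason.
#'
#' @param table measurement table (after [estimate_phalanx4()] if desired).
#' @param tree calibrated `phylo`.
#' @param order predictor preference order (element column names). The
#'   default works distally-in along the wing finger, then humerus, then
#'   mandible.
#' @param exclude taxa excluded from regression fitting (never from the
#'   output).
#' @param elements element set summed into a wingspan.
#' @return a trait-vector `data.frame` (`taxon`, `value` log10 m, `se`,
#'   `provenance`), with the per-predictor fit table in
#'   `attr(, "predictor_fits")`.
#' @export
estimate_wingspan_cascade <- function(table, tree,
                                      order = c("phIV2", "phIV1", "humerus", "mandible"),
                                      exclude = character(),
                                      elements = wingspan_elements()) {
  direct_val <- vapply(seq_len(nrow(table)), function(i)
    compute_wingspan(table[i, ], elements), 0)
  imput_se <- if ("phIV4_se_log10" %in% names(table)) table$phIV4_se_log10 else rep(0, nrow(table))
  imput <- if ("phIV4_imputed" %in% names(table)) table$phIV4_imputed else rep(FALSE, nrow(table))
  direct_se <- ifelse(is.na(direct_val), NA_real_, 0)
  if (any(imput)) {
    # delta method: d log10(W) / d log10(ph4) = ph4 / W (in mm)
    idx <- which(imput & !is.na(direct_val))
    if (length(idx)) {
      Wmm <- rowSums(table[idx, elements, drop = FALSE]) # unscaled sum
      direct_se[idx] <- (table$phIV4[idx] / Wmm) * imput_se[idx]
    }
  }

  has_direct <- !is.na(direct_val)
  y <- stats::setNames(direct_val[has_direct], table$taxon[has_direct])
  fit_y <- y[!(names(y) %in% exclude)]
  candidates <- unique(c(order, setdiff(element_columns(), c(elements, "radius")), "ulna", "radius"))
  candidates <- intersect(candidates, names(table))
  preds <- lapply(candidates, function(el) {
    v <- table[[el]]
    keep <- !is.na(v) & !(if (el == "phIV4") imput else FALSE)
    stats::setNames(log10(v[keep]), table$taxon[keep])
  })
  names(preds) <- candidates
  # 5 complete cases minimum: enough for the 3-parameter fixed-lambda fits
  # to carry a defined AICc
  usable <- vapply(preds, function(p)
    length(intersect(intersect(names(p), names(fit_y)), tree$tip.label)) >= 5L, TRUE)
  fits <- select_predictor(preds[usable], fit_y, tree)

  rows <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    tx <- table$taxon[i]
    if (has_direct[i]) {
      rows[[i]] <- data.frame(taxon = tx, value = direct_val[i],
                              se = direct_se[i], provenance = "measured",
                              stringsAsFactors = FALSE)
      next
    }
    done <- FALSE
    for (el in order) {
      v <- preds[[el]][tx]
      frow <- fits[fits$predictor == el, , drop = FALSE]
      if (!is.na(v) && nrow(frow) == 1L) {
        est <- frow$intercept + frow$slope * unname(v)
        # rescale the predicted wingspan like a measured one
        est <- est + log10(table$rescale_factor[i] %||% 1)
        rows[[i]] <- data.frame(taxon = tx, value = est, se = frow$msee,
                                provenance = paste0("estimated:", el),
                                stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
    }
    if (!done) {
      message(sprintf("estimate_wingspan_cascade: %s has no usable predictor; excluded", tx))
      rows[[i]] <- NULL
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictor_fits") <- fits
  attr(out, "n_direct") <- sum(has_direct)
  out
}

#' Count taxa with directly computable wingspans
#'
#' A taxon is directly computable when every configured wing element is
#' present (before any phalanx IV-4 imputation unless `table` has already
#' been imputed).
#'
#' @param table measurement table.
#' @param elements element set summed into a wingspan.
#' @return integer count.
#' @export
count_direct_wingspans <- function(table, elements = wingspan_elements()) {
  imput <- if ("phIV4_imputed" %in% names(table)) table$phIV4_imputed else rep(FALSE, nrow(table))
  ok <- stats::complete.cases(table[elements])
  sum(ok & !imput)
}

#' Assemble the adult trait vector from raw inputs
#'
#' Convenience wrapper running the full trait-assembly stage: adult
#' filtering, phalanx IV-4 imputation, then the wingspan cascade.
#'
#' @inheritParams estimate_wingspan_cascade
#' @param adults_only drop juvenile/subadult taxa first (default TRUE).
#' @return trait-vector `data.frame` (see [estimate_wingspan_cascade()]).
#' @export
assemble_traits <- function(table, tree, order = c("phIV2", "phIV1", "humerus", "mandible"),
                            exclude = character(), elements = wingspan_elements(),
                            adults_only = TRUE) {
  if (adults_only) table <- filter_adults(table)
  table <- estimate_phalanx4(table, tree, exclude = exclude)
  estimate_wingspan_cascade(table, tree, order = order, exclude = exclude,
                            elements = elements)
}
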