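#' Infection percentage, survey convention
#'
#' `100 * infected / screened`, rounded to one decimal -- the format
#' used throughout survey prevalence tables.
#'
#' @param infected,screened non-negative counts (vectorized).
#' @return Numeric percentages rounded to one decimal.
#' @examples
#' pct(119, 271)  # 43.9
#' @export
pct <- function(infected, screened) {
  round(100 * infected / screened, 1)
}

#' Prevalence table
#'
#' Aggregates screening results into infected / screened counts and
#' percentages per group, with a totals row. Accepts either a
#' specimen table (one row per individual, see [as_specimen_table()])
#' or a pre-aggregated count table with `infected` and `screened`
#' columns (e.g. per species x locality counts transcribed from a
#' survey report).
#'
#' @param x a `specimen_table`, or a data frame with `infected`,
#'   `screened` and grouping columns.
#' @param by grouping column(s), default `"species"`.
#' @return Data frame (class `prevalence_table`) with the grouping
#'   columns, `infected`, `screened`, `percent`; the totals are in
#'   `attr(, "total")`. Groups with zero screened individuals are
#'   omitted.
#' @export
prevalence_table <- function(x, by = "species") {
  missing <- setdiff(by, names(x))
  if (length(missing)) {
    sym_stop("symbio_bad_columns",
             paste("unknown grouping column(s):", paste(missing, collapse = ", ")))
  }
  if (all(c("infected", "screened") %in% names(x))) {
    counts <- x[, c(by, "infected", "screened"), drop = FALSE]
  } else {
    x <- as_specimen_table(as.data.frame(x))
    counts <- data.frame(x[, by, drop = FALSE],
                         infected = as.integer(x$overall == "positive"),
                         screened = 1L)
  }
  key <- interaction(counts[, by, drop = FALSE], drop = TRUE, lex.order = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(counts)), key), function(idx) {
    row <- counts[idx[1L], by, drop = FALSE]
    row$infected <- sum(counts$infected[idx])
    row$screened <- sum(counts$screened[idx])
    row
  }))
  rownames(agg) <- NULL
  agg <- agg[agg$screened > 0L, , drop = FALSE]
  agg$percent <- pct(agg$infected, agg$screened)
  total <- c(infected = sum(agg$infected), screened = sum(agg$screened))
  attr(agg, "total") <- c(total, percent = pct(total[["infected"]],
                                               total[["screened"]]))
  class(agg) <- c("prevalence_table", "data.frame")
  agg
}

#' @export
print.prevalence_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  tot <- attr(x, "total")
  cat(sprintf("Total: %d/%d (%.1f%%)\n", tot[["infected"]], tot[["screened"]],
              tot[["percent"]]))
  invisible(x)
}

#' Cochran's Q test for matched binary responses
#'
#' Tests whether k matched binary conditions (e.g. infection calls in
#' leg, gut and reproductive tissue of the same individuals) share a
#' common positive rate:
#' \deqn{Q = (k-1)\,\frac{k \sum_j C_j^2 - (\sum_j C_j)^2}
#'                      {k \sum_i R_i - \sum_i R_i^2}}
#' with column totals \eqn{C_j} and row totals \eqn{R_i}; `Q` is
#' compared to a chi-square with `k - 1` degrees of freedom.
#' Subjects positive or negative everywhere contribute nothing (their
#' terms cancel); the number of informative subjects is reported, and
#' with zero informative subjects the test is undefined and flagged.
#'
#' @param m binary matrix, subjects x conditions (no missing values).
#' @return List of class `cochran_q`: `Q`, `df`, `p`,
#'   `n_informative`, `n`, `col_totals`, `undefined`.
#' @export
cochran_q <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    sym_stop("symbio_bad_value", "matrix must be complete and binary")
  }
  k <- ncol(m)
  if (k < 2L) sym_stop("symbio_too_few", "need at least two conditions")
  R <- rowSums(m); C <- colSums(m)
  informative <- sum(R > 0 & R < k)
  den <- k * sum(R) - sum(R^2)
  if (informative == 0L || den == 0) {
    return(structure(list(Q = NA_real_, df = k - 1L, p = NA_real_,
                          n_informative = informative, n = nrow(m),
                          col_totals = C, undefined = TRUE),
                     class = "cochran_q"))
  }
  Q <- (k - 1) * (k * sum(C^2) - sum(C)^2) / den
  structure(list(Q = Q, df = k - 1L, p = pchisq(Q, k - 1L, lower.tail = FALSE),
                 n_informative = informative, n = nrow(m), col_totals = C,
                 undefined = FALSE),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  if (x$undefined) {
    cat("Cochran's Q: undefined (no informative subjects)\n")
  } else {
    cat(sprintf("Cochran's Q = %.4g, df = %d, P = %.4g (%d informative of %d subjects)\n",
                x$Q, x$df, x$p, x$n_informative, x$n))
  }
  invisible(x)
}

#' Pairwise McNemar post hoc tests
#'
#' For every unordered pair of conditions, tests the discordant
#' counts b (first positive only) and c (second positive only).
#' Default is the exact two-sided binomial test of b successes in
#' b + c trials at probability one half; `"chisq"` and
#' `"chisq-cc"` give the uncorrected and continuity-corrected
#' chi-square versions. Degenerate pairs (b = c = 0) get P = 1 and a
#' flag.
#'
#' @param m binary matrix, subjects x conditions.
#' @param method `"exact"`, `"chisq"`, or `"chisq-cc"`.
#' @param adjust multiplicity adjustment across pairs
#'   (`p.adjust` method; default `"none"`, the raw post hoc
#'   convention).
#' @return Data frame: `cond1`, `cond2`, `b`, `c`, `statistic`, `p`,
#'   `p_adjusted`, `degenerate`.
#' @export
mcnemar_pairwise <- function(m, method = c("exact", "chisq", "chisq-cc"),
                             adjust = "none") {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    sym_stop("symbio_bad_value", "matrix must be complete and binary")
  }
  cn <- colnames(m) %||% paste0("C", seq_len(ncol(m)))
  pairs <- combn(ncol(m), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    b <- sum(m[, i] == 1 & m[, j] == 0)
    cc <- sum(m[, i] == 0 & m[, j] == 1)
    degenerate <- (b + cc) == 0L
    if (degenerate) {
      stat <- NA_real_; p <- 1
    } else if (method == "exact") {
      stat <- NA_real_
      p <- binom.test(b, b + cc, 0.5)$p.value
    } else {
      num <- if (method == "chisq") (b - cc)^2 else (abs(b - cc) - 1)^2
      stat <- num / (b + cc)
      p <- pchisq(stat, 1L, lower.tail = FALSE)
    }
    data.frame(cond1 = cn[i], cond2 = cn[j], b = b, c = cc,
               statistic = stat, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p, method = adjust)
  out
}

#' Tissue-tropism analysis of a specimen table
#'
#' Restricts to internal-control-passing specimens with a call in all
#' three tissues, then runs [cochran_q()] and [mcnemar_pairwise()].
#'
#' @param t a `specimen_table`.
#' @param method,adjust passed to [mcnemar_pairwise()].
#' @return List: `counts` (per-tissue positives, n, percent), `q`
#'   (Cochran), `pairs` (McNemar data frame), `n`.
#' @export
tissue_tropism <- function(t, method = "exact", adjust = "none") {
  t <- as_specimen_table(as.data.frame(t))
  keep <- t$control_pass &
    t$leg != "not-assessed" & t$gut != "not-assessed" &
    t$reproductive != "not-assessed"
  t <- t[keep, , drop = FALSE]
  m <- cbind(leg = as.integer(t$leg == "positive"),
             gut = as.integer(t$gut == "positive"),
             reproductive = as.integer(t$reproductive == "positive"))
  counts <- data.frame(tissue = colnames(m), positive = colSums(m),
                       n = nrow(m), percent = pct(colSums(m), nrow(m)),
                       row.names = NULL)
  list(counts = counts, q = cochran_q(m),
       pairs = mcnemar_pairwise(m, method, adjust), n = nrow(m))
}

#' Subset species with balanced sex representation
#'
#' Keeps only species where the rarer sex amounts to at least
#' `min_ratio` of the commoner sex (inclusive boundary); species with
#' one sex absent are dropped. Used before sex-effect regression so a
#' lopsided species cannot masquerade as a sex effect.
#'
#' @param t a `specimen_table`.
#' @param min_ratio minimum minor/major sex ratio (default 0.6).
#' @return The filtered `specimen_table`; kept species in
#'   `attr(, "species_kept")`.
#' @export
sex_balance_subset <- function(t, min_ratio = 0.6) {
  t <- as_specimen_table(as.data.frame(t))
  tab <- table(t$species, t$sex)
  nF <- tab[, match("F", colnames(tab))]
  nM <- if ("M" %in% colnames(tab)) tab[, "M"] else 0 * nF
  ok <- nF > 0 & nM > 0 & pmin(nF, nM) / pmax(nF, nM) >= min_ratio
  keep <- rownames(tab)[ok]
  out <- t[t$species %in% keep, , drop = FALSE]
  class(out) <- c("specimen_table", "data.frame")
  attr(out, "species_kept") <- keep
  out
}

#' Sex effect on infection (binary logistic regression)
#'
#' Fits `infection ~ sex` by iteratively reweighted least squares
#' (logit link) and reports the male-versus-female odds ratio with its
#' Wald test. Optionally applies [sex_balance_subset()] first, the
#' standard guard against species-driven sex imbalance.
#'
#' @param t a `specimen_table`.
#' @param apply_balance apply the balance rule first (default FALSE).
#' @param min_ratio balance threshold when applied.
#' @return List of class `sex_effect`: `odds_ratio`, `coefficient`
#'   (log odds ratio for males), `se`, `z`, `df` (n - 2), `p`,
#'   `subset` (species kept, n, percent male), `separation`.
#' @export
logistic_sex_effect <- function(t, apply_balance = FALSE, min_ratio = 0.6) {
  t <- as_specimen_table(as.data.frame(t))
  species_kept <- unique(t$species)
  if (apply_balance) {
    t <- sex_balance_subset(t, min_ratio)
    species_kept <- attr(t, "species_kept")
  }
  if (length(unique(t$sex)) < 2L) {
    sym_stop("symbio_too_few", "both sexes must be present")
  }
  y <- as.integer(t$overall == "positive")
  if (length(unique(y)) < 2L) {
    sym_stop("symbio_too_few", "both infection outcomes must be present")
  }
  male <- as.integer(t$sex == "M")
  # complete separation: one sex all one outcome and the other all the other
  sep <- length(unique(y[male == 1L])) == 1L &&
    length(unique(y[male == 0L])) == 1L && y[male == 1L][1L] != y[male == 0L][1L]
  if (sep) {
    return(structure(list(odds_ratio = NA_real_, coefficient = NA_real_,
                          se = NA_real_, z = NA_real_, df = length(y) - 2L,
                          p = NA_real_,
                          subset = list(species = species_kept, n = length(y),
                                        percent_male = pct(sum(male), length(y))),
                          separation = TRUE),
                     class = "sex_effect"))
  }
  fit <- suppressWarnings(
    glm(y ~ male, family = binomial(), control = list(epsilon = 1e-8, maxit = 100)))
  cf <- summary(fit)$coefficients
  beta <- cf["male", "Estimate"]; se <- cf["male", "Std. Error"]
  structure(list(odds_ratio = exp(beta), coefficient = beta, se = se,
                 z = beta / se, df = length(y) - 2L,
                 p = 2 * pnorm(-abs(beta / se)),
                 subset = list(species = species_kept, n = length(y),
                               percent_male = pct(sum(male), length(y))),
                 separation = FALSE),
            class = "sex_effect")
}

#' @export
print.sex_effect <- function(x, ...) {
  if (x$separation) {
    cat("Sex effect: complete separation, no estimate\n")
  } else {
    cat(sprintf(
      "Sex effect (M vs F): OR = %.3f, Z = %.2f, df = %d, P = %.4g (n = %d, %.1f%% male)\n",
      x$odds_ratio, x$z, x$df, x$p, x$subset$n, x$subset$percent_male))
  }
  invisible(x)
}
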