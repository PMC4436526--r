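## Fisher r-to-Z aggregation and the 2x2 within-subject condition tests
## (univariate contrast F tests and Hotelling T-squared for the variable
## triples, reported Pillai-style with partial eta squared).

#' Fisher r-to-Z transformation and its inverse
#'
#' `fisher_z()` maps a correlation to `Z = 0.5 * ln((1 + r) / (1 - r))`, the
#' variance-stabilising transform that makes correlation means amenable to
#' parametric statistics; `inverse_fisher()` is `tanh(Z)`. Correlations of
#' magnitude 1 transform to infinity, so `fisher_z()` refuses them; callers
#' aggregating near-perfect synthetic correlations clip at `1 - 1e-7`.
#'
#' @param r correlation(s), `|r| < 1`.
#' @param z Fisher-Z value(s).
#' @return numeric vector of the same length.
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stop("fisher_z requires finite |r| < 1; clip or exclude perfect correlations")
  0.5 * log((1 + r) / (1 - r))
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(z) {
  if (any(!is.finite(z))) stop("inverse_fisher requires finite Z")
  tanh(z)
}

#' Assemble the per-person condition summary table
#'
#' Collects a list of [dyad_coupling()] fits (one per person per crossed
#' condition) into the long condition table the 2x2 tests run on: one row
#' per person, feedback condition, difficulty condition and dependent
#' variable, carrying the across-trial mean absolute correlation, mean
#' Fisher Z and mean lag. The table must be complete: every person needs all
#' four crossed conditions.
#'
#' @param fits list of `dyad_coupling` objects.
#' @return a data frame of class `condition_table` with columns `person_id`,
#'   `feedback`, `difficulty`, `dv`, `r_abs_mean`, `z_mean`, `lag_mean_s`.
#' @export
build_condition_table <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "dyad_coupling")))
  rows <- lapply(fits, function(f)
    cbind(person_id = f$person_id, feedback = f$feedback,
          difficulty = f$difficulty, f$means))
  tab <- do.call(rbind, rows)
  for (p in unique(tab$person_id)) {
    have <- unique(tab[tab$person_id == p, c("feedback", "difficulty")])
    want <- expand.grid(feedback = c("face_to_face", "video"),
                        difficulty = c("simple", "complex"),
                        stringsAsFactors = FALSE)
    miss <- !mapply(function(fb, df) any(have$feedback == fb & have$difficulty == df),
                    want$feedback, want$difficulty)
    if (any(miss))
      stop("person ", p, " is missing condition(s): ",
           paste(want$feedback[miss], want$difficulty[miss], sep = "/",
                 collapse = ", "))
  }
  class(tab) <- c("condition_table", "data.frame")
  tab
}

person_contrasts <- function(tab, dvs, measure_col,
                             effect = c("feedback", "difficulty", "interaction")) {
  effect <- match.arg(effect)
  persons <- unique(tab$person_id)
  D <- matrix(NA_real_, length(persons), length(dvs),
              dimnames = list(persons, dvs))
  for (i in seq_along(persons)) {
    sub <- tab[tab$person_id == persons[i], ]
    for (j in seq_along(dvs)) {
      y <- function(fb, df)
        sub[[measure_col]][sub$feedback == fb & sub$difficulty == df &
                           sub$dv == dvs[j]]
      D[i, j] <- switch(effect,
        feedback = mean(c(y("face_to_face", "simple"), y("face_to_face", "complex"))) -
                   mean(c(y("video", "simple"), y("video", "complex"))),
        difficulty = mean(c(y("face_to_face", "simple"), y("video", "simple"))) -
                     mean(c(y("face_to_face", "complex"), y("video", "complex"))),
        interaction = (y("face_to_face", "simple") - y("face_to_face", "complex")) -
                      (y("video", "simple") - y("video", "complex")))
    }
  }
  D
}

uni_contrast_test <- function(d) {
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(c(F = 0, df1 = 1, df2 = n - 1, p = 1, pes = 0))
    stop("zero between-person variance with a nonzero effect: degenerate F")
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  F <- t^2
  c(F = F, df1 = 1, df2 = n - 1,
    p = stats::pf(F, 1, n - 1, lower.tail = FALSE),
    pes = F / (F + n - 1))
}

hotelling_test <- function(D) {
  n <- nrow(D); p <- ncol(D)
  if (n <= p) stop("need more persons than dependent variables (n > ", p, ")")
  if (all(D == 0)) return(c(F = 0, df1 = p, df2 = n - p, p = 1, pes = 0))
  S <- stats::cov(D)
  m <- colMeans(D)
  T2 <- tryCatch(n * drop(t(m) %*% solve(S, m)),
                 error = function(e) stop("singular contrast covariance: degenerate test"))
  F <- (n - p) / (p * (n - 1)) * T2
  c(F = F, df1 = p, df2 = n - p,
    p = stats::pf(F, p, n - p, lower.tail = FALSE),
    pes = T2 / (T2 + n - 1))
}

#' Within-subject 2x2 factorial tests on the condition table
#'
#' Runs the repeated-measures tests of the 2x2 feedback-by-difficulty design
#' on one dependent-variable set: for the triples (joint angles q1-q3, or
#' grip position x/y/z) a multivariate test per effect (one-sample Hotelling
#' T-squared on the per-person within-subject contrasts, F with df
#' `(3, n - 3)`) plus univariate contrast F tests per variable (df
#' `(1, n - 1)`, identical to the squared paired t statistic); for grip
#' aperture the univariate test alone. Effects are the feedback main effect,
#' the difficulty main effect and their interaction; each row reports F,
#' degrees of freedom, p and partial eta squared.
#'
#' @param table a [build_condition_table()] result, or any data frame with
#'   columns `person_id`, `feedback`, `difficulty`, `dv` and the measure
#'   column.
#' @param dv_set `"grip_position"` (grip_x/y/z), `"joint_angles"` (q1-q3) or
#'   `"aperture"`.
#' @param measure `"Z"` (tests `z_mean`) or `"lag"` (tests `lag_mean_s`).
#' @return a data frame of class `dyad_rm_test` with one row per effect and
#'   scope.
#' @export
rm_2x2_test <- function(table,
                        dv_set = c("grip_position", "joint_angles", "aperture"),
                        measure = c("Z", "lag")) {
  dv_set <- match.arg(dv_set)
  measure <- match.arg(measure)
  col <- if (measure == "Z") "z_mean" else "lag_mean_s"
  if (!col %in% names(table)) stop("table lacks a '", col, "' column")
  dvs <- switch(dv_set, grip_position = c("grip_x", "grip_y", "grip_z"),
                joint_angles = c("q1", "q2", "q3"), aperture = "aperture")
  tab <- table[table$dv %in% dvs, , drop = FALSE]
  n <- length(unique(tab$person_id))
  if (n < 3L) stop("need at least 3 persons")
  counts <- table(tab$person_id)
  if (length(unique(counts)) != 1L || unique(counts) != 4L * length(dvs))
    stop("unbalanced table: every person needs all 4 conditions for each variable")
  effects <- c("feedback", "difficulty", "interaction")
  out <- NULL
  for (eff in effects) {
    D <- person_contrasts(tab, dvs, col, eff)
    if (length(dvs) > 1L) {
      h <- hotelling_test(D)
      out <- rbind(out, data.frame(effect = eff, scope = "multivariate",
                                   dv = paste(dvs, collapse = ","),
                                   F = h["F"], df1 = h["df1"], df2 = h["df2"],
                                   p = h["p"], partial_eta_sq = h["pes"]))
    }
    for (j in seq_along(dvs)) {
      u <- uni_contrast_test(D[, j])
      out <- rbind(out, data.frame(effect = eff, scope = "univariate",
                                   dv = dvs[j],
                                   F = u["F"], df1 = u["df1"], df2 = u["df2"],
                                   p = u["p"], partial_eta_sq = u["pes"]))
    }
  }
  rownames(out) <- NULL
  attr(out, "measure") <- measure
  attr(out, "n") <- n
  class(out) <- c("dyad_rm_test", "data.frame")
  out
}

#' @export
print.dyad_rm_test <- function(x, ...) {
  cat(sprintf("Within-subject 2x2 tests on mean %s (n = %d persons)\n",
              if (attr(x, "measure") == "Z") "Fisher Z" else "lag (s)",
              attr(x, "n")))
  df <- as.data.frame(x)
  df$F <- round(df$F, 3)
  df$p <- signif(df$p, 3)
  df$partial_eta_sq <- round(df$partial_eta_sq, 3)
  df$df <- sprintf("(%d, %d)", df$df1, df$df2)
  print(df[, c("effect", "scope", "dv", "F", "df", "p", "partial_eta_sq")],
        row.names = FALSE)
  invisible(x)
}
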