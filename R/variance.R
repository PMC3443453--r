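## Multinomial delta-method variance engine.
##
## Every two-locus statistic T here is a smooth function of the nine cell
## proportions q (which are multinomial with covariance
## Sigma_kl = (delta_kl q_k - q_k q_l)/n), so Var(T) ~= g' Sigma g with
## g = dT/dq. Adding any multiple of the all-ones vector to g does not change
## g' Sigma g (Sigma annihilates it), so gradients may be taken treating the
## nine cells as free coordinates. The quadratic form is nonnegative, hence
## this engine never produces negative variances (closed-form textbook
## variances can; see oobFilter).

.o <- function(s, v) outer(s, v)    # per-pair scalar x fixed 9-pattern

## Analytic gradients (P x 9) of the core statistics. `st` is .diseqStats(Q).
.gradients <- function(Q, st) {
  X <- .CELL_X; Y <- .CELL_Y
  P <- nrow(Q)
  one <- rep(1, P)
  eAA <- as.numeric(X == 2); eBB <- as.numeric(Y == 2)
  gDelta <- .o(one, X * Y / 2) - .o(st$p_B, X) - .o(st$p_A, Y)
  gDA <- .o(one, eAA) - .o(st$p_A, X)
  gDB <- .o(one, eBB) - .o(st$p_B, Y)
  gDAAB <- .o(one, eAA * Y / 2) - .o(st$p_A * st$p_B, X) -
    .o(st$p_A^2 / 2, Y) - .o(st$D_A / 2, Y) - gDA * st$p_B -
    .o(st$delta_AB / 2, X) - gDelta * st$p_A
  gDABB <- .o(one, X * eBB / 2) - .o(st$p_A * st$p_B, Y) -
    .o(st$p_B^2 / 2, X) - .o(st$D_B / 2, X) - gDB * st$p_A -
    .o(st$delta_AB / 2, Y) - gDelta * st$p_B
  gOmega <- .o(one, eAA * eBB) - .o(st$P_BB, eAA) - .o(st$P_AA, eBB)
  gDAABB <- .o(one, eAA * eBB) - .o(st$P_BB, eAA) - .o(st$P_AA, eBB) -
    .o(st$d_ABB, X) - gDABB * (2 * st$p_A) -
    .o(st$d_AAB, Y) - gDAAB * (2 * st$p_B) -
    .o(st$p_B * st$delta_AB, X) - .o(st$p_A * st$delta_AB, Y) -
    gDelta * (2 * st$p_A * st$p_B + 2 * st$delta_AB)
  list(p_A = .o(one, X / 2), D_A = gDA, delta_AB = gDelta,
       d_AAB = gDAAB, d_ABB = gDABB, delta_AABB = gDAABB,
       omega_AABB = gOmega)
}

## g' Sigma g for each row; n may be a scalar or per-row vector.
.quadForm <- function(Q, G, n) {
  (rowSums(Q * G^2) - rowSums(Q * G)^2) / n
}

#' Delta-method sampling variance of a two-locus disequilibrium statistic
#'
#' Large-sample variance of a statistic of the nine unphased two-locus
#' genotype proportions under multinomial sampling of n diploids:
#' Var = g' Sigma g, with g the gradient of the statistic in the cell
#' proportions (analytic for the built-in statistics, central differences
#' with step 1e-6 otherwise) and Sigma the multinomial covariance of the
#' proportions.
#'
#' @param counts 3x3 genotype count table (see [twoLocusCounts()]).
#' @param statistic one of `"delta_AB"`, `"d_AAB"`, `"d_ABB"`,
#'   `"delta_AABB"`, `"omega_AABB"`, `"D_A"`, `"p_A"`; ignored when
#'   `statFun` is supplied.
#' @param statFun optional function taking a length-9 proportion vector (in
#'   cell order g00, g01, g02, g10, ..., g22) and returning a scalar; its
#'   variance is computed by numeric differentiation. This is the plug-in
#'   slot for user-supplied closed-form statistics.
#' @param method `"analytic"` (default for built-ins) or `"numeric"`.
#' @return the variance estimate (numeric scalar), `NA` if the statistic is
#'   undefined for the table (e.g. monomorphic locus).
#' @examples
#' # Var(p_A) at HWE, p = 0.5, n = 1023: 0.25 / 2046
#' tab <- matrix(c(256, 512, 255, 0, 0, 0, 0, 0, 0), 3, 3)
#' deltaVariance(tab, "p_A")
#' @export
deltaVariance <- function(counts,
                          statistic = c("delta_AB", "d_AAB", "d_ABB",
                                        "delta_AABB", "omega_AABB",
                                        "D_A", "p_A"),
                          statFun = NULL,
                          method = c("analytic", "numeric")) {
  row <- .asCellRow(counts)
  Q <- row$Q; n <- row$n
  if (!is.finite(n) || n < 2) stop("need a count table with n >= 2")
  if (!is.null(statFun)) return(.numericDeltaVar(Q, n, statFun))
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  if (method == "numeric") {
    f <- function(q) {
      s <- .diseqStats(matrix(q, 1, 9))
      if (statistic == "D_A") s$D_A else s[[statistic]]
    }
    return(.numericDeltaVar(Q, n, f))
  }
  st <- .diseqStats(Q)
  if (st$monomorphic && statistic %in% c("delta_AB", "d_AAB", "d_ABB", "delta_AABB"))
    return(NA_real_)
  G <- .gradients(Q, st)[[statistic]]
  max(.quadForm(Q, G, n), 0)
}

.numericDeltaVar <- function(Q, n, f, h = 1e-6) {
  q <- drop(Q)
  g <- vapply(seq_len(9L), function(k) {
    qp <- q; qm <- q
    qp[k] <- qp[k] + h; qm[k] <- qm[k] - h
    (f(qp) - f(qm)) / (2 * h)
  }, numeric(1))
  if (any(!is.finite(g))) return(NA_real_)
  max((sum(q * g^2) - sum(q * g)^2) / n, 0)
}

## The full per-pair inference table used by pairDiseq() and scanPairs().
## Q: P x 9 proportions, n: per-row pairwise-complete counts (Inf allowed =
## population mode, where sampling quantities are NA).
.pairEngine <- function(Q, n, emTol = 1e-10, emMaxIter = 1000L,
                        zygotic = c("designated", "opposite")) {
  st <- .diseqStats(Q, zygotic = zygotic)
  em <- .emGametic(Q, tol = emTol, maxIter = emMaxIter)
  finite <- is.finite(n)
  G <- .gradients(Q, st)
  nn <- ifelse(finite, n, NA_real_)
  vAAB <- pmax(.quadForm(Q, G$d_AAB, nn), 0)
  vABB <- pmax(.quadForm(Q, G$d_ABB, nn), 0)
  vAABB <- pmax(.quadForm(Q, G$delta_AABB, nn), 0)
  und <- st$monomorphic
  vAAB[und] <- NA_real_; vABB[und] <- NA_real_; vAABB[und] <- NA_real_
  out <- cbind(st,
               em[, c("d_gametic", "r2_gld", "em_converged", "em_flat")],
               data.frame(n = nn,
                          var_d_AAB = vAAB, var_d_ABB = vABB,
                          var_delta_AABB = vAABB))
  out$r2_gld[und] <- NA_real_
  safe_ratio <- function(num, den) ifelse(is.na(den) | den <= 0, NA_real_, num / den)
  out$x2_gld <- nn * out$r2_gld
  out$x2_cld <- nn * out$r2_cld
  out$x2_zld <- nn * out$r2_zld
  out$x2_d_AAB <- safe_ratio(out$d_AAB^2, vAAB)
  out$x2_d_ABB <- safe_ratio(out$d_ABB^2, vABB)
  out$x2_delta_AABB <- safe_ratio(out$delta_AABB^2, vAABB)
  for (comp in c("gld", "cld", "zld", "d_AAB", "d_ABB", "delta_AABB"))
    out[[paste0("phi2_", comp)]] <- out[[paste0("x2_", comp)]] / nn
  out
}

#' All disequilibrium estimates and tests for one marker pair
#'
#' Applies the complete estimator hierarchy to a single 3x3 unphased
#' genotype table: composite digenic LD (Delta_AB), EM gametic LD, both
#' trigenic disequilibria, the composite quadrigenic disequilibrium
#' (Delta_AABB), zygotic LD (omega_AABB), squared correlations, and the
#' one-df chi-square statistic and generalized squared correlation
#' (phi2 = X2/n) for each component. Digenic and zygotic tests use
#' X2 = n r2 (for composite LD, equivalently n Delta^2 / [(pi_A + D_A)
#' (pi_B + D_B)]); trigenic and quadrigenic tests use X2 = est^2 / Var with
#' the delta-method variance.
#'
#' If `counts` is a probability table (sums to 1), the estimators run in
#' population mode: exact parameter values are returned and all sampling
#' quantities (variances, X2, phi2) are `NA`. This is the n -> infinity
#' plug-in identity used to derive generator truths.
#'
#' @param counts 3x3 genotype count (or probability) table; or a length-9
#'   vector in cell order g00, g01, ..., g22.
#' @param n overrides the total count (rarely needed).
#' @param emTol,emMaxIter EM controls, see [emGameticLD()].
#' @param zygotic which double homozygote defines the zygotic LD omega:
#'   `"designated"` (the AA/BB corner of the designated A alleles — the
#'   minor alleles after [qcFilter()]) or `"opposite"` (the aa/bb corner).
#'   The choice changes omega and the ZLD test (the two corners are not
#'   equivalent), not any other component.
#' @return one-row data.frame with estimates, variances, `x2_*`, `phi2_*`
#'   and flags (`monomorphic`, `em_converged`, `em_flat`).
#' @examples
#' w1 <- matrix(0, 3, 3); w1[1, 1] <- 50; w1[3, 3] <- 50  # 50 aabb + 50 AABB
#' pairDiseq(w1)[, c("delta_AB", "delta_AABB", "omega_AABB", "x2_cld")]
#' @export
pairDiseq <- function(counts, n = NULL, emTol = 1e-10, emMaxIter = 1000L,
                      zygotic = c("designated", "opposite")) {
  row <- .asCellRow(counts, n)
  .pairEngine(row$Q, row$n, emTol = emTol, emMaxIter = emMaxIter,
              zygotic = zygotic)
}

#' Per-component chi-square tests for one marker pair
#'
#' Long-format view of [pairDiseq()]: one row per component with its
#' estimate, variance (where the test is variance-based), X2, phi2,
#' significance at `alpha` against the 1-df chi-square quantile, and the
#' phi2 range status used by [oobFilter()].
#'
#' @inheritParams pairDiseq
#' @param alpha test size (default 0.05; critical value 3.84 at 2 d.p.).
#' @return data.frame with columns `component`, `estimate`, `variance`,
#'   `chisq`, `phi2`, `significant`, `oob_status`.
#' @export
componentChisq <- function(counts, n = NULL, alpha = 0.05,
                           zygotic = c("designated", "opposite")) {
  p <- pairDiseq(counts, n, zygotic = zygotic)
  comp <- c(GLD = "gld", CLD = "cld", ZLD = "zld",
            D_AAB = "d_AAB", D_ABB = "d_ABB", Delta_AABB = "delta_AABB")
  est <- c(p$d_gametic, p$delta_AB, p$omega_AABB, p$d_AAB, p$d_ABB, p$delta_AABB)
  v <- c(NA, NA, NA, p$var_d_AAB, p$var_d_ABB, p$var_delta_AABB)
  x2 <- unlist(p[paste0("x2_", comp)], use.names = FALSE)
  phi2 <- unlist(p[paste0("phi2_", comp)], use.names = FALSE)
  crit <- qchisq(1 - alpha, df = 1)
  data.frame(component = names(comp), estimate = est, variance = v,
             chisq = x2, phi2 = phi2,
             significant = !is.na(x2) & x2 > crit,
             oob_status = ifelse(is.na(phi2), NA_character_,
                                 ifelse(phi2 < 0, "below-zero",
                                        ifelse(phi2 > 1, "above-one", "in-range"))),
             row.names = NULL)
}

#' Filter generalized squared correlations to the admissible range [0, 1]
#'
#' phi2 = X2/n is only interpretable as a squared-correlation-like measure
#' inside [0, 1]; values outside (possible when a closed-form variance
#' estimate is negative, or for extreme tables) are trimmed before
#' summarization, and the two out-of-bound situations are tallied
#' separately. With the default delta-method variance engine phi2 < 0
#' cannot occur (the variance is a nonnegative quadratic form), so the
#' below-zero tally is only exercised by user-supplied variance functions.
#'
#' @param phi2 numeric vector of phi-square values (NA = undefined test,
#'   excluded from both the retained set and the tallies).
#' @return list with `retained` (values in [0,1]), `keep` (logical index
#'   into the input), `n_below` (phi2 < 0), `n_above` (phi2 > 1), `n_undefined`.
#' @examples
#' oobFilter(c(0.3, -0.1, 1.2))  # keeps 0.3; one below, one above
#' @export
oobFilter <- function(phi2) {
  def <- !is.na(phi2)
  below <- def & phi2 < 0
  above <- def & phi2 > 1
  keep <- def & !below & !above
  list(retained = phi2[keep], keep = keep,
       n_below = sum(below), n_above = sum(above), n_undefined = sum(!def))
}

#' Empirical power: the rejection rate of 1-df chi-square tests
#'
#' The fraction of defined tests whose X2 exceeds the (1 - alpha) quantile
#' of the 1-df chi-square distribution. When the tested null is true this
#' "power" equals the significance level — the calibration property used
#' throughout the genome-scan summaries. Undefined (NA) statistics are
#' excluded from the denominator.
#'
#' @param chisq numeric vector of chi-square statistics.
#' @param alpha significance level.
#' @return proportion significant, with attributes `n_tests` (denominator)
#'   and `n_excluded`.
#' @examples
#' powerEstimate(c(4, 3, 10))  # 2/3 exceed 3.8415
#' @export
powerEstimate <- function(chisq, alpha = 0.05) {
  def <- !is.na(chisq)
  if (!any(def)) stop("no defined test statistics")
  crit <- qchisq(1 - alpha, df = 1)
  out <- mean(chisq[def] > crit)
  attr(out, "n_tests") <- sum(def)
  attr(out, "n_excluded") <- sum(!def)
  out
}
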