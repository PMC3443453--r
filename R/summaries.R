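.COMPONENTS <- c("gld", "cld", "zld", "d_AAB", "d_ABB", "delta_AABB")

## distance bin edges (bp) reproducing the canonical <=5 Mb intervals
.DEFAULT_BIN_EDGES <- c(0, 0.025, 0.05, 0.075, 0.1, 0.2, 0.5, 1.5, 3, 5) * 1e6

.binLabels <- function(edges) {
  mb <- edges / 1e6
  paste0("[", mb[-length(mb)], ",", mb[-1], ")")
}

## power + strength of one component over a set of scan rows, after
## trimming phi2 to [0, 1]
.componentCell <- function(rows, comp, alpha = 0.05, threshold = 0.25) {
  phi2 <- rows[[paste0("phi2_", comp)]]
  x2 <- rows[[paste0("x2_", comp)]]
  f <- oobFilter(phi2)
  n <- length(f$retained)
  crit <- qchisq(1 - alpha, df = 1)
  data.frame(component = comp, n_pairs = n,
             mean_phi2 = if (n) mean(f$retained) else NA_real_,
             sd_phi2 = if (n > 1) sd(f$retained) else NA_real_,
             frac_ge_threshold = if (n) mean(f$retained >= threshold) else NA_real_,
             power = if (n) mean(x2[f$keep] > crit) else NA_real_,
             n_below = f$n_below, n_above = f$n_above,
             n_undefined = f$n_undefined)
}

#' Summarize LD strength and test power by physical-distance bin
#'
#' Groups syntenic scan rows into half-open distance intervals [lo, hi) and
#' reports, per bin and component: the number of retained pairs (phi2 in
#' [0, 1]), mean and SD of phi2, the fraction of pairs with phi2 at or
#' above `threshold`, and the empirical test power at `alpha`.
#'
#' @param rows scan rows from [scanPairs()] (non-syntenic rows are dropped).
#' @param edgesBp increasing vector of bin edges in bp; default the nine
#'   canonical intervals up to 5 Mb (25, 50, 75, 100, 200, 500 kb, 1.5, 3,
#'   5 Mb).
#' @param components which components to summarize.
#' @param threshold phi2 strength threshold (default 0.25).
#' @param alpha test size.
#' @return long data.frame: `bin`, `bin_lo_bp`, `bin_hi_bp`, `component`,
#'   `n_pairs`, `mean_phi2`, `sd_phi2`, `frac_ge_threshold`, `power`,
#'   out-of-bound tallies.
#' @export
binByDistance <- function(rows, edgesBp = .DEFAULT_BIN_EDGES,
                          components = c("gld", "cld", "zld"),
                          threshold = 0.25, alpha = 0.05) {
  rows <- rows[rows$syntenic & !is.na(rows$distance_bp), , drop = FALSE]
  if (!nrow(rows)) stop("no syntenic rows with defined distance")
  bin <- cut(rows$distance_bp, breaks = edgesBp, right = FALSE,
             labels = .binLabels(edgesBp))
  labs <- levels(bin)
  out <- do.call(rbind, lapply(seq_along(labs), function(b) {
    sub <- rows[!is.na(bin) & bin == labs[b], , drop = FALSE]
    cells <- do.call(rbind, lapply(components, function(comp) {
      if (nrow(sub)) .componentCell(sub, comp, alpha, threshold)
      else data.frame(component = comp, n_pairs = 0L, mean_phi2 = NA_real_,
                      sd_phi2 = NA_real_, frac_ge_threshold = NA_real_,
                      power = NA_real_, n_below = 0L, n_above = 0L,
                      n_undefined = 0L)
    }))
    cbind(data.frame(bin = labs[b], bin_lo_bp = edgesBp[b],
                     bin_hi_bp = edgesBp[b + 1]), cells)
  }))
  rownames(out) <- NULL
  out
}

#' Per-chromosome power for linked vs unlinked marker pairs
#'
#' Splits syntenic pairs at a physical-distance cutoff (by convention 50 Mb
#' under the 1 cM = 1 Mb equivalence: pairs farther apart are treated as
#' freely recombining) and reports empirical power per chromosome,
#' component and group. Chromosomes with no pairs beyond the cutoff (too
#' short) report `NA` for the unlinked group.
#'
#' @param rows scan rows from [scanPairs()].
#' @param cutoffBp linked/unlinked cutoff, default 5e7 (<= is linked).
#' @param components,alpha see [binByDistance()].
#' @return data.frame: `chrom`, `group` ("linked"/"unlinked"), `component`,
#'   `n_pairs`, `power`.
#' @export
linkedUnlinkedSummary <- function(rows, cutoffBp = 5e7,
                                  components = .COMPONENTS, alpha = 0.05) {
  rows <- rows[rows$syntenic & !is.na(rows$distance_bp), , drop = FALSE]
  if (!nrow(rows)) stop("no syntenic rows")
  out <- list()
  for (ch in unique(rows$chrom_i)) {
    sub <- rows[rows$chrom_i == ch, , drop = FALSE]
    for (grp in c("linked", "unlinked")) {
      g <- if (grp == "linked") sub[sub$distance_bp <= cutoffBp, , drop = FALSE]
           else sub[sub$distance_bp > cutoffBp, , drop = FALSE]
      for (comp in components) {
        cell <- if (nrow(g)) .componentCell(g, comp, alpha)
                else data.frame(component = comp, n_pairs = 0L, power = NA_real_)
        out[[length(out) + 1L]] <-
          data.frame(chrom = ch, group = grp, component = comp,
                     n_pairs = cell$n_pairs, power = cell$power)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Test power by minor-allele-frequency class of the two loci
#'
#' Assigns every pair to one of nine (MAF_A, MAF_B) classes — intervals
#' [0, 0.1), [0.1, 0.3) and [0.3, 0.5] (half-open, closed top) on the
#' pairwise-complete MAFs — and reports per class and component the mean,
#' minimum and maximum of the per-group empirical power, where groups are
#' chromosomes for syntenic pairs and chromosome pairs for non-syntenic
#' pairs.
#'
#' @param rows scan rows from [scanPairs()] (syntenic and/or non-syntenic).
#' @param breaks MAF class breakpoints.
#' @param components,alpha see [binByDistance()].
#' @return data.frame: `syntenic`, `maf_class_A`, `maf_class_B`,
#'   `component`, `n_pairs`, `n_groups`, `mean_power`, `min_power`,
#'   `max_power`.
#' @export
mafClassSummary <- function(rows, breaks = c(0, 0.1, 0.3, 0.5),
                            components = .COMPONENTS, alpha = 0.05) {
  classify <- function(maf) cut(maf, breaks = breaks, right = FALSE,
                                include.lowest = TRUE)
  clsA <- classify(rows$maf_A)
  clsB <- classify(rows$maf_B)
  group <- ifelse(rows$syntenic, rows$chrom_i,
                  paste(rows$chrom_i, rows$chrom_j, sep = ":"))
  crit <- qchisq(1 - alpha, df = 1)
  out <- list()
  for (syn in intersect(c(TRUE, FALSE), unique(rows$syntenic))) {
    for (a in levels(clsA)) for (b in levels(clsB)) {
      sel <- rows$syntenic == syn & !is.na(clsA) & !is.na(clsB) &
        clsA == a & clsB == b
      for (comp in components) {
        phi2 <- rows[[paste0("phi2_", comp)]][sel]
        x2 <- rows[[paste0("x2_", comp)]][sel]
        keep <- oobFilter(phi2)$keep
        grp <- group[sel][keep]
        pw <- if (any(keep)) tapply(x2[keep] > crit, grp, mean) else numeric(0)
        out[[length(out) + 1L]] <- data.frame(
          syntenic = syn, maf_class_A = a, maf_class_B = b, component = comp,
          n_pairs = sum(keep), n_groups = length(pw),
          mean_power = if (length(pw)) mean(pw) else NA_real_,
          min_power = if (length(pw)) min(pw) else NA_real_,
          max_power = if (length(pw)) max(pw) else NA_real_)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Empirical power as a function of marker distance
#'
#' Bins syntenic pairs into consecutive distance windows of width
#' `windowBp` up to `maxBp` and reports, per window and component, the
#' rejection rate of the 1-df chi-square test among retained
#' (phi2-in-range) pairs — the decay-of-power curve as a plottable table.
#'
#' @param rows scan rows from [scanPairs()].
#' @param windowBp window width in bp.
#' @param maxBp largest distance considered (default 50 Mb).
#' @param components,alpha see [binByDistance()].
#' @return data.frame: `window_lo_bp`, `window_hi_bp`, `midpoint_bp`,
#'   `component`, `n_pairs`, `power`.
#' @export
powerVsDistanceCurve <- function(rows, windowBp, maxBp = 5e7,
                                 components = .COMPONENTS, alpha = 0.05) {
  edges <- seq(0, maxBp, by = windowBp)
  if (edges[length(edges)] < maxBp) edges <- c(edges, maxBp)
  rows <- rows[rows$syntenic & !is.na(rows$distance_bp) &
                 rows$distance_bp <= maxBp, , drop = FALSE]
  if (!nrow(rows)) stop("no syntenic rows within maxBp")
  win <- findInterval(rows$distance_bp, edges, rightmost.closed = TRUE)
  out <- list()
  for (w in seq_len(length(edges) - 1L)) {
    sub <- rows[win == w, , drop = FALSE]
    for (comp in components) {
      cell <- if (nrow(sub)) .componentCell(sub, comp, alpha)
              else data.frame(n_pairs = 0L, power = NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        window_lo_bp = edges[w], window_hi_bp = edges[w + 1L],
        midpoint_bp = (edges[w] + edges[w + 1L]) / 2, component = comp,
        n_pairs = cell$n_pairs, power = cell$power)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Out-of-bound phi-square tallies per component
#'
#' Counts, per component (optionally per chromosome), how many pairs had
#' phi2 below 0 or above 1 and were therefore excluded from summaries.
#' With the delta-method variance engine the below-zero column is
#' structurally zero; it is reported anyway because user-supplied
#' closed-form variances can be negative.
#'
#' @param rows scan rows from [scanPairs()].
#' @param by `"all"` or `"chrom"`.
#' @param components which components to tally.
#' @return data.frame with counts and proportions of the two out-of-bound
#'   situations.
#' @export
oobSummary <- function(rows, by = c("all", "chrom"),
                       components = .COMPONENTS) {
  by <- match.arg(by)
  groups <- if (by == "chrom") split(rows, rows$chrom_i) else list(all = rows)
  out <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    for (comp in components) {
      f <- oobFilter(sub[[paste0("phi2_", comp)]])
      n_def <- length(f$retained) + f$n_below + f$n_above
      out[[length(out) + 1L]] <- data.frame(
        group = g, component = comp, n_defined = n_def,
        n_below = f$n_below, n_above = f$n_above,
        prop_below = if (n_def) f$n_below / n_def else NA_real_,
        prop_above = if (n_def) f$n_above / n_def else NA_real_)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
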