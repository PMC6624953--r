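# Change-point detection of 3' ends downstream of the stop codon.
#
# Coverage downstream of a stop codon from nested APA isoforms is, in
# expectation, a non-increasing staircase: each polyA site drops the depth by
# the abundance of the isoforms ending there. The detector fits a
# piecewise-constant Poisson mean by binary segmentation and keeps only
# sustained drops that pass the min_fold criterion, which separates exon
# boundary change points from local coverage dips.

#' Segmentation and scan parameters
#'
#' @param min_fold Fold-change criterion for accepting a change point: a
#'   split is kept when downstream/upstream mean depth is at most `min_fold`.
#'   Larger values are more permissive (default 0.8).
#' @param merge_radius Maximum zero-coverage gap (nt) bridged while scanning;
#'   a longer gap truncates the scan (default 200).
#' @param max_isoform Cap on the number of coverage segments per gene
#'   (default 20).
#' @param precision_window Resolution (nt) of 3' end calls; ends closer than
#'   this merge into one polyA site (fixed at 100 by the read-level limits of
#'   short-read data).
#' @param min_segment_len Minimum segment length (nt); defaults to the
#'   precision window, since change points below the resolution are not
#'   meaningful.
#' @param scan_cap Maximum scan length (nt) downstream of the stop codon.
#' @param split_penalty BIC-type acceptance penalty multiplier: a split is
#'   accepted only when it improves the Poisson log-likelihood by more than
#'   `split_penalty * log(L)` (L = scanned length; a change point adds two
#'   free parameters, each worth `log(L)/2` under BIC). Default 1; 0
#'   disables the penalty. This is what separates sustained coverage drops
#'   from chance fluctuations at low depth.
#' @return A `seg_params` list.
#' @export
seg_params <- function(min_fold = 0.8, merge_radius = 200, max_isoform = 20,
                       precision_window = 100, min_segment_len = precision_window,
                       scan_cap = 20000, split_penalty = 1) {
  stopifnot(min_fold > 0, min_fold <= 1, merge_radius > 0, max_isoform >= 1,
            precision_window > 0, min_segment_len > 0,
            min_segment_len <= scan_cap, split_penalty >= 0)
  structure(list(min_fold = min_fold, merge_radius = merge_radius,
                 max_isoform = max_isoform, precision_window = precision_window,
                 min_segment_len = min_segment_len, scan_cap = scan_cap,
                 split_penalty = split_penalty),
            class = "seg_params")
}

#' Project coverage downstream of the stop codon into 3'UTR coordinates
#'
#' Extracts the per-base depth vector in mRNA orientation starting at 3'UTR
#' position 1 (first base after the stop codon). The scan is bounded by the
#' mask-region edge, the nearest neighboring gene's CDS edge, and `scan_cap`;
#' zero-coverage runs longer than `merge_radius` truncate it, and trailing
#' zeros are trimmed so the last element is the last covered base.
#'
#' @param track `coverage_track` for the gene's mask region.
#' @param gene One-row gene-model tibble.
#' @param neighbors Gene-model tibble of other genes (used to stop the scan
#'   at the nearest downstream CDS edge); may be empty or NULL.
#' @param params `seg_params`.
#' @return Numeric depth vector `v[1..L]`; length 0 when the gene is
#'   unannotatable (stop anchor at the region edge or no downstream
#'   coverage). Attribute `truncated_at_gap` records gap truncation.
#' @export
scan_region <- function(track, gene, neighbors = NULL, params = seg_params()) {
  a <- gene$stop_anchor
  if (gene$strand == "+") {
    room <- track$end - a
  } else {
    room <- a - track$start
  }
  if (room <= 0) return(numeric(0))
  L <- min(params$scan_cap, room)
  if (!is.null(neighbors) && nrow(neighbors) > 0) {
    nb <- neighbors[neighbors$gene_id != gene$gene_id &
                      neighbors$chrom == gene$chrom, ]
    if (nrow(nb) > 0) {
      if (gene$strand == "+") {
        edges <- nb$cds_start[nb$cds_start >= a] - a
      } else {
        edges <- a - nb$cds_end[nb$cds_end <= a]
      }
      if (length(edges) > 0) L <- min(L, edges)
    }
  }
  if (L <= 0) return(numeric(0))
  idx <- if (gene$strand == "+") {
    (a - track$start) + seq_len(L)
  } else {
    (a - track$start) + 1 - seq_len(L)
  }
  v <- track$depth[idx]
  truncated <- FALSE
  # truncate at the first zero-run longer than merge_radius
  r <- rle(v == 0)
  long <- which(r$values & r$lengths > params$merge_radius)
  if (length(long) > 0) {
    cut <- if (long[1] == 1) 0 else sum(r$lengths[seq_len(long[1] - 1)])
    truncated <- any(v[seq.int(cut + 1, length(v))] > 0)
    v <- v[seq_len(cut)]
  }
  # trim trailing zeros: the extinction end is the last covered base
  nz <- which(v > 0)
  v <- if (length(nz) == 0) numeric(0) else v[seq_len(max(nz))]
  attr(v, "truncated_at_gap") <- truncated
  v
}

# Poisson segment cost: negative log-likelihood up to data-only constants.
# S * (1 - log(S/L)) for a segment with sum S and length L; 0 when S = 0.
.seg_cost <- function(S, L) {
  ifelse(S == 0, 0, S - S * log(S / L))
}

# Best split of v[l..r] under the length constraint; returns NULL or
# list(t, improvement, accept) where accept applies the drop, min_fold and
# penalty rules. `penalty` is the precomputed BIC threshold for the scan.
.best_split <- function(cum, l, r, params, penalty) {
  m <- params$min_segment_len
  ts <- seq.int(l + m - 1, r - m)
  if (length(ts) == 0 || ts[1] > ts[length(ts)]) return(NULL)
  S <- cum[r + 1] - cum[l]
  S1 <- cum[ts + 1] - cum[l]
  S2 <- S - S1
  L1 <- ts - l + 1
  L2 <- r - ts
  cost <- .seg_cost(S1, L1) + .seg_cost(S2, L2)
  best <- max(which(cost == min(cost)))  # tie toward the most downstream split
  t <- ts[best]
  up <- S1[best] / L1[best]
  down <- S2[best] / L2[best]
  improvement <- .seg_cost(S, r - l + 1) - cost[best]
  accept <- up > 0 && down < up && (down / up) <= params$min_fold &&
    improvement > penalty
  list(t = t, improvement = improvement, accept = accept, up = up, down = down)
}

#' Change-point segmentation of a 3'UTR coverage vector
#'
#' Binary segmentation under a piecewise-constant Poisson mean model: at each
#' step the split minimizing the total negative log-likelihood is taken,
#' provided both child segments reach `min_segment_len`, the downstream mean
#' is lower than the upstream mean, and their ratio is at most `min_fold`.
#' Splitting stops when no acceptable split remains or `max_isoform` segments
#' exist. The returned ends are the accepted split positions plus the
#' extinction end (last covered base).
#'
#' @param v Depth vector in 3'UTR coordinates (from [scan_region()]).
#' @param params `seg_params`.
#' @return Tibble of ends sorted by `utr_pos`: `utr_pos`, `upstream_mean`,
#'   `downstream_mean`, `drop_ratio`, `kind` (`"changepoint"` or
#'   `"extinction"`). Empty for an all-zero or empty vector.
#' @export
segment_changepoints <- function(v, params = seg_params()) {
  empty <- tibble::tibble(utr_pos = integer(), upstream_mean = numeric(),
                          downstream_mean = numeric(), drop_ratio = numeric(),
                          kind = character())
  nz <- which(v > 0)
  if (length(nz) == 0) return(empty)
  n <- max(nz)  # ignore any trailing zeros
  cum <- c(0, cumsum(as.numeric(v[seq_len(n)])))
  penalty <- params$split_penalty * log(n)
  segs <- list(c(1L, n))
  repeat {
    if (length(segs) >= params$max_isoform) break
    cands <- lapply(segs, function(s) .best_split(cum, s[1], s[2], params,
                                                  penalty))
    ok <- vapply(cands, function(x) !is.null(x) && x$accept, logical(1))
    if (!any(ok)) break
    imp <- vapply(cands, function(x) if (is.null(x)) -Inf else x$improvement,
                  numeric(1))
    imp[!ok] <- -Inf
    tpos <- vapply(cands, function(x) if (is.null(x)) -1L else x$t, numeric(1))
    pick <- which(imp == max(imp))
    pick <- pick[which.max(tpos[pick])]
    s <- segs[[pick]]
    t <- cands[[pick]]$t
    segs[[pick]] <- c(s[1], t)
    segs[[length(segs) + 1L]] <- c(t + 1L, s[2])
  }
  bounds <- sort(vapply(segs, `[`, numeric(1), 2))
  means <- vapply(seq_along(bounds), function(i) {
    l <- if (i == 1) 1 else bounds[i - 1] + 1
    (cum[bounds[i] + 1] - cum[l]) / (bounds[i] - l + 1)
  }, numeric(1))
  tibble::tibble(
    utr_pos = as.integer(bounds),
    upstream_mean = means,
    downstream_mean = c(means[-1], 0)[seq_along(bounds)],
    drop_ratio = c(means[-1], 0)[seq_along(bounds)] / means,
    kind = c(rep("changepoint", length(bounds) - 1), "extinction"))
}

#' Filter and flag detected 3' ends
#'
#' Ends within the CDS cannot occur by construction (the scan starts after
#' the stop codon) but the guard is kept; ends closer than 100 nt to the stop
#' are retained and flagged `very_short`, since their position — and later
#' their abundance estimate — is less reliable.
#'
#' @param ends Tibble from [segment_changepoints()].
#' @param very_short_below 3'UTR length (nt) under which an end is flagged
#'   (strict `<`; default 100).
#' @return `ends` with rows at `utr_pos < 1` removed and a `very_short`
#'   column added.
#' @export
filter_ends <- function(ends, very_short_below = 100) {
  ends <- ends[ends$utr_pos >= 1, , drop = FALSE]
  ends$very_short <- ends$utr_pos < very_short_below
  ends
}

#' Detect 3' ends for one gene
#'
#' Convenience wrapper: project coverage with [scan_region()], segment with
#' [segment_changepoints()], flag with [filter_ends()], and attach genomic
#' coordinates.
#'
#' @inheritParams scan_region
#' @return Tibble of ends with `gene_id`, `utr_pos`, `genomic_pos` (0-based
#'   position of the isoform's last base), detection statistics and flags.
#' @export
detect_ends <- function(track, gene, neighbors = NULL, params = seg_params()) {
  v <- scan_region(track, gene, neighbors, params)
  ends <- filter_ends(segment_changepoints(v, params))
  ends$gene_id <- rep(gene$gene_id, nrow(ends))
  ends$genomic_pos <- if (gene$strand == "+") {
    gene$stop_anchor + ends$utr_pos - 1
  } else {
    gene$stop_anchor - ends$utr_pos
  }
  ends[, c("gene_id", "utr_pos", "genomic_pos", "upstream_mean",
           "downstream_mean", "drop_ratio", "kind", "very_short")]
}
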