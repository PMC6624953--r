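# Polyadenylation-signal hexamer scanning around called 3' ends.
#
# Sequences are handled in the DNA alphabet (AATAAA/ATTAAA for the canonical
# signals written AAUAAA/AUUAAA on the mRNA). Positions are 3'UTR coordinates
# (nt after stop, position 1 = first base after the stop codon) on the
# mRNA-sense strand, so a - strand gene's sequence must be reverse
# complemented before scanning (see utr_sequence()).

#' Canonical polyadenylation-signal hexamers
#'
#' @return Character vector `c("AATAAA", "ATTAAA")` (DNA alphabet).
#' @export
canonical_pas <- function() c("AATAAA", "ATTAAA")

#' Default variant polyadenylation-signal hexamers
#'
#' The 16 most common non-canonical hexamers observed at mouse polyA sites.
#' The list ships as an editable plain-text config file
#' (`system.file("extdata", "pas_variants.txt", package = "utrapa")`); pass
#' your own file to use a different set.
#'
#' @param path Optional path to a hexamer list (one per line, `#` comments).
#' @return Character vector of hexamers.
#' @export
variant_pas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pas_variants.txt", package = "utrapa")
  }
  x <- readLines(path)
  x <- toupper(trimws(x[!grepl("^#", x) & nzchar(trimws(x))]))
  bad <- x[nchar(x) != 6 | grepl("[^ACGT]", x)]
  if (length(bad) > 0) stop("invalid hexamer(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  x
}

#' Extract the mRNA-sense 3'UTR scan sequence of a gene
#'
#' @param region_seq A `Biostrings::DNAString`/character of a mask region's
#'   genomic sequence (plus strand).
#' @param region_start 0-based genomic start of `region_seq`.
#' @param gene One-row gene-model tibble.
#' @param length Number of nt after the stop codon to extract (clipped to
#'   the region edge).
#' @return Character string in mRNA orientation; position 1 is 3'UTR
#'   position 1.
#' @export
utr_sequence <- function(region_seq, region_start, gene, length = 20000) {
  s <- as.character(region_seq)
  n <- nchar(s)
  a <- gene$stop_anchor
  if (gene$strand == "+") {
    from <- a - region_start + 1
    to <- min(n, from + length - 1)
    if (from > n || from < 1) return("")
    substr(s, from, to)
  } else {
    to <- a - region_start
    from <- max(1, to - length + 1)
    if (to < 1 || to > n) return("")
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(s, from, to))))
  }
}

#' Scan a sequence for hexamer matches
#'
#' Exact matching, overlaps allowed.
#'
#' @param seq mRNA-sense sequence (character, DNA alphabet; `N` permitted and
#'   never matches).
#' @param hexamers Character vector of 6-mers.
#' @return Tibble of `hexamer`, `utr_pos` (position of the hexamer's first
#'   base), sorted by position.
#' @export
scan_hexamers <- function(seq, hexamers) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence contains non-ACGTN characters",
                                   call. = FALSE)
  if (length(hexamers) == 0 || nchar(seq) < 6) {
    return(tibble::tibble(hexamer = character(), utr_pos = integer()))
  }
  hits <- lapply(hexamers, function(h) {
    m <- gregexpr(paste0("(?=", h, ")"), seq, perl = TRUE)[[1]]
    pos <- as.integer(m[m > 0])
    if (length(pos) == 0) return(NULL)
    tibble::tibble(hexamer = h, utr_pos = pos)
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) return(tibble::tibble(hexamer = character(), utr_pos = integer()))
  dplyr::arrange(out, .data$utr_pos, .data$hexamer)
}

#' Match hexamer hits to a polyA site
#'
#' A hexamer matches a site when its offset (hexamer start minus 3' end
#' position) to any member end of the site lies in `window` (endpoints
#' inclusive). One match is reported per hexamer position, against the
#' member end with the smallest absolute offset.
#'
#' @param members Numeric vector of the site's member 3' end positions.
#' @param hits Hexamer hit tibble from [scan_hexamers()].
#' @param window Length-2 numeric window on the offset; default
#'   `c(-100, 100)`.
#' @param kind Label stored in the result (`"canonical"` or `"variant"`).
#' @return Tibble: `hexamer`, `pas_pos`, `end_pos`, `offset`, `kind`.
#' @export
match_pas <- function(members, hits, window = c(-100, 100), kind = "canonical") {
  empty <- tibble::tibble(hexamer = character(), pas_pos = integer(),
                          end_pos = numeric(), offset = numeric(),
                          kind = character())
  if (nrow(hits) == 0 || length(members) == 0) return(empty)
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    off <- hits$utr_pos[i] - members
    ok <- off >= window[1] & off <= window[2]
    if (!any(ok)) return(NULL)
    best <- which(ok)[order(abs(off[ok]), members[ok])][1]
    tibble::tibble(hexamer = hits$hexamer[i], pas_pos = hits$utr_pos[i],
                   end_pos = members[best], offset = off[best], kind = kind)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty else out
}

#' Match variant hexamers upstream of a cleavage position
#'
#' Used only for 3' ends lacking any canonical signal; the window is
#' upstream-only (`[-100, 0]`, inclusive).
#'
#' @param cleavage_pos 3' end position (nt after stop).
#' @param hits Variant hexamer hits from [scan_hexamers()].
#' @param window Offset window, default `c(-100, 0)`.
#' @return Tibble as in [match_pas()] with `kind = "variant"`.
#' @export
match_variant_pas <- function(cleavage_pos, hits, window = c(-100, 0)) {
  match_pas(cleavage_pos, hits, window = window, kind = "variant")
}

#' Annotate polyA sites with PAS matches
#'
#' Scans each gene's 3'UTR sequence for canonical hexamers in a
#' `[-100, +100]` window around any member end of each site; sites with no
#' canonical match are rescanned for variant hexamers in the upstream-only
#' `[-100, 0]` window from their representative end.
#'
#' @param sites Per-gene polyA site tibble (with `gene_id`).
#' @param utr_seqs Named list/character vector of mRNA-sense 3'UTR sequences
#'   keyed by `gene_id` (see [utr_sequence()]).
#' @param variants Character vector of variant hexamers
#'   (default [variant_pas()]).
#' @param window Canonical match window, default `c(-100, 100)`.
#' @return List: `matches` (tibble of `gene_id`, `site`, `hexamer`,
#'   `pas_pos`, `end_pos`, `offset`, `kind`) and `sites` (input with a
#'   `has_canonical` column).
#' @export
annotate_pas <- function(sites, utr_seqs, variants = variant_pas(),
                         window = c(-100, 100)) {
  matches <- list()
  has_canon <- rep(FALSE, nrow(sites))
  for (gid in unique(sites$gene_id)) {
    seq <- utr_seqs[[gid]]
    if (is.null(seq) || !nzchar(seq)) next
    canon_hits <- scan_hexamers(seq, canonical_pas())
    var_hits <- NULL
    rows <- which(sites$gene_id == gid)
    for (i in rows) {
      m <- match_pas(sites$members[[i]], canon_hits, window = window)
      if (nrow(m) > 0) {
        has_canon[i] <- TRUE
      } else {
        if (is.null(var_hits)) var_hits <- scan_hexamers(seq, variants)
        m <- match_variant_pas(sites$representative_end[i], var_hits)
      }
      if (nrow(m) > 0) {
        m$gene_id <- gid
        m$site <- sites$site[i]
        matches[[length(matches) + 1L]] <- m
      }
    }
  }
  matches <- if (length(matches) > 0) dplyr::bind_rows(matches) else
    tibble::tibble(hexamer = character(), pas_pos = integer(),
                   end_pos = numeric(), offset = numeric(), kind = character(),
                   gene_id = character(), site = integer())
  sites$has_canonical <- has_canon
  list(matches = matches[, c("gene_id", "site", "hexamer", "pas_pos",
                             "end_pos", "offset", "kind")],
       sites = sites)
}
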