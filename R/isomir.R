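# isomiR calling: reconstruct a read from a canonical mature miRNA under a
# bounded edit space (terminal trimming/extension, at most one internal
# substitution), categorize the edit, and summarize dominant isomiR types.
#
# Offset convention: negative = trimmed, positive = extended (nt), at the
# respective end of the canonical sequence. Substitution positions are
# 1-based on the canonical. 3' extensions are treated as non-templated (any
# base); extension bases never count as substitutions.

#' Apply an isomiR edit to a canonical sequence
#'
#' @param canonical Canonical mature sequence (DNA alphabet).
#' @param d5,d3 Terminal offsets (negative = trim, positive = extend).
#' @param sub_pos 1-based substitution position on the canonical, or `NA`.
#' @param sub_to Replacement base, or `NA`.
#' @param ext5,ext3 Extension bases (must have `max(0, d5)` / `max(0, d3)`
#'   characters).
#' @return The edited read sequence.
#' @export
apply_isomir_edit <- function(canonical, d5 = 0L, d3 = 0L,
                              sub_pos = NA_integer_, sub_to = NA_character_,
                              ext5 = "", ext3 = "") {
  L <- nchar(canonical)
  a <- max(0L, -d5); b <- max(0L, -d3)
  if (L - a - b < 1L) stop("edit removes the whole sequence")
  if (nchar(ext5) != max(0L, d5) || nchar(ext3) != max(0L, d3))
    stop("extension bases inconsistent with offsets")
  core <- substr(canonical, a + 1L, L - b)
  if (!is.na(sub_pos)) {
    if (sub_pos <= a || sub_pos > L - b)
      stop("substitution position outside the retained core")
    k <- sub_pos - a
    if (substr(core, k, k) == sub_to)
      stop("substitution must change the base")
    substr(core, k, k) <- sub_to
  }
  paste0(ext5, core, ext3)
}

#' Enumerate every legal single isomiR edit of a canonical sequence
#'
#' One edit at a time: all 5' offsets within `max5` (extensions over all four
#' bases), all 3' offsets within `max3` (extensions over the non-templated
#' {A,T} alphabet), and all single-base substitutions. Edits that would
#' shorten the read below `min_len` are not legal and are skipped.
#'
#' @param canonical Canonical sequence.
#' @param max5,max3 Terminal offset bounds (nt).
#' @param min_len Minimum legal read length.
#' @param seed_span 1-based inclusive seed positions, for the category of
#'   substitution edits.
#' @return `data.frame` with columns `read`, `category`, `d5`, `d3`,
#'   `sub_pos`, `sub_to`.
#' @export
enumerate_single_edits <- function(canonical, max5 = 2L, max3 = 4L,
                                   min_len = 15L, seed_span = c(2L, 8L)) {
  L <- nchar(canonical)
  rows <- list()
  add <- function(read, category, d5, d3, sub_pos, sub_to) {
    rows[[length(rows) + 1L]] <<- data.frame(
      read = read, category = category, d5 = d5, d3 = d3,
      sub_pos = sub_pos, sub_to = sub_to, stringsAsFactors = FALSE)
  }
  ext_combos <- function(k, alphabet) {
    do.call(paste0, rev(expand.grid(rep(list(alphabet), k),
                                    stringsAsFactors = FALSE)))
  }
  for (d5 in setdiff(seq.int(-max5, max5), 0L)) {
    if (L + d5 < min_len) next
    if (d5 < 0) {
      add(apply_isomir_edit(canonical, d5 = d5), "FIVE_PRIME", d5, 0L,
          NA_integer_, NA_character_)
    } else {
      for (e in ext_combos(d5, c("A", "C", "G", "T")))
        add(apply_isomir_edit(canonical, d5 = d5, ext5 = e), "FIVE_PRIME",
            d5, 0L, NA_integer_, NA_character_)
    }
  }
  for (d3 in setdiff(seq.int(-max3, max3), 0L)) {
    if (L + d3 < min_len) next
    if (d3 < 0) {
      add(apply_isomir_edit(canonical, d3 = d3), "THREE_PRIME", 0L, d3,
          NA_integer_, NA_character_)
    } else {
      for (e in ext_combos(d3, c("A", "T")))
        add(apply_isomir_edit(canonical, d3 = d3, ext3 = e), "THREE_PRIME",
            0L, d3, NA_integer_, NA_character_)
    }
  }
  in_seed <- function(p) p >= seed_span[1] && p <= seed_span[2]
  for (p in seq_len(L)) {
    from <- substr(canonical, p, p)
    for (to in setdiff(c("A", "C", "G", "T"), from)) {
      add(apply_isomir_edit(canonical, sub_pos = p, sub_to = to),
          if (in_seed(p)) "SUBSTITUTION_SEED" else "SUBSTITUTION_NONSEED",
          0L, 0L, p, to)
    }
  }
  do.call(rbind, rows)
}

count_mismatches <- function(x, y) {
  sum(charToRaw(x) != charToRaw(y))
}

#' Match a read against mature miRNAs with isomiR tolerance
#'
#' Finds the minimal-edit reconstruction of the read from some canonical
#' sequence: terminal offsets within `max5`/`max3`, at most one internal
#' substitution, extension bases unconstrained (3' additions may be
#' non-templated). The cost order is lexicographic
#' (substitutions, |5' offset|, |3' offset|), so a read explainable as pure
#' 3' variation is never called a substitution variant. Ties across
#' canonicals are broken by miRNA name, making the result independent of the
#' ordering of the miRNA set.
#'
#' @param read Read sequence (DNA alphabet, post-trim).
#' @param mirnas A [mature_mirna_set].
#' @param max5,max3 Terminal offset bounds (nt).
#' @param min_len Minimum read length considered.
#' @return A list (`mirna`, `d5`, `d3`, `sub_pos`, `sub_from`, `sub_to`,
#'   `in_seed`, `category`) or `NULL` when no canonical admits a
#'   reconstruction.
#' @export
isomir_match <- function(read, mirnas, max5 = 2L, max3 = 4L, min_len = 15L) {
  stopifnot(inherits(mirnas, "mature_mirna_set"))
  n <- nchar(read)
  if (n < min_len) return(NULL)
  seed_span <- mirnas$seed_span
  best <- NULL
  best_cost <- c(Inf, Inf, Inf, Inf, Inf)
  nm <- names(mirnas$sequences)
  ord <- order(nm)  # name order => set-order independence
  for (i in ord) {
    canonical <- mirnas$sequences[[i]]
    L <- nchar(canonical)
    for (d5 in seq.int(-max5, max5)) {
      d3 <- n - L - d5
      if (d3 < -max3 || d3 > max3) next
      a <- max(0L, -d5); b <- max(0L, -d3)
      e5 <- max(0L, d5); e3 <- max(0L, d3)
      core_len <- L - a - b
      if (core_len < 1L) next
      core_read <- substr(read, e5 + 1L, e5 + core_len)
      core_can <- substr(canonical, a + 1L, L - b)
      mm <- count_mismatches(core_read, core_can)
      if (mm > 1L) next
      cost <- c(mm, abs(d5), abs(d3), d5, d3)
      better <- FALSE
      for (k in seq_along(cost)) {
        if (cost[k] < best_cost[k]) { better <- TRUE; break }
        if (cost[k] > best_cost[k]) break
      }
      if (!better) next
      sub_pos <- NA_integer_; sub_from <- NA_character_; sub_to <- NA_character_
      if (mm == 1L) {
        k <- which(charToRaw(core_read) != charToRaw(core_can))[1]
        sub_pos <- a + k
        sub_from <- substr(core_can, k, k)
        sub_to <- substr(core_read, k, k)
      }
      best_cost <- cost
      best <- list(mirna = nm[i], d5 = as.integer(d5), d3 = as.integer(d3),
                   sub_pos = sub_pos, sub_from = sub_from, sub_to = sub_to,
                   in_seed = !is.na(sub_pos) && sub_pos >= seed_span[1] &&
                     sub_pos <= seed_span[2])
    }
  }
  if (is.null(best)) return(NULL)
  best$category <- isomir_categorize(best)
  best
}

#' Categorize an isomiR call
#'
#' `CANONICAL` if no edits; `FIVE_PRIME` / `THREE_PRIME` for a single
#' terminal offset; `BOTH_ENDS` for two offsets without substitution;
#' `SUBSTITUTION_SEED` / `SUBSTITUTION_NONSEED` for a lone substitution
#' (inside / outside the seed region); `MIXED` otherwise.
#'
#' @param call An isomiR call as returned by [isomir_match()].
#' @return Category string.
#' @export
isomir_categorize <- function(call) {
  has_sub <- !is.na(call$sub_pos)
  d5 <- call$d5 != 0L
  d3 <- call$d3 != 0L
  if (!has_sub) {
    if (!d5 && !d3) return("CANONICAL")
    if (d5 && !d3) return("FIVE_PRIME")
    if (!d5 && d3) return("THREE_PRIME")
    return("BOTH_ENDS")
  }
  if (!d5 && !d3)
    return(if (isTRUE(call$in_seed)) "SUBSTITUTION_SEED" else "SUBSTITUTION_NONSEED")
  "MIXED"
}

#' Dominant isomiR type per miRNA and group-level distribution
#'
#' For each miRNA the category with the highest read count is its dominant
#' type; a tie involving `CANONICAL` resolves to `CANONICAL`, other ties to
#' the lexicographically first category (ties are reported). The group
#' distribution is the fraction of miRNAs per dominant type; the fraction of
#' all miRNA reads carrying any variation is reported alongside.
#'
#' @param calls `data.frame` with columns `mirna` and `category` (one row
#'   per miRNA-assigned read of one sample group).
#' @param mirnas Optional character vector restricting the summarized miRNAs
#'   (e.g. those passing the media filter).
#' @return List with `per_mirna` (miRNA, dominant category, read count,
#'   tie flag), `distribution` (fraction of miRNAs per dominant type) and
#'   `variant_read_fraction`.
#' @export
isomir_dominance <- function(calls, mirnas = NULL) {
  stopifnot(all(c("mirna", "category") %in% names(calls)))
  if (!is.null(mirnas)) calls <- calls[calls$mirna %in% mirnas, , drop = FALSE]
  if (nrow(calls) == 0L) stop("no isomiR calls to summarize")
  tab <- table(calls$mirna, factor(calls$category, levels = ISOMIR_CATEGORIES))
  dominant <- character(nrow(tab)); tie <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    v <- tab[i, ]
    top <- names(v)[v == max(v)]
    tie[i] <- length(top) > 1L
    dominant[i] <- if ("CANONICAL" %in% top) "CANONICAL" else sort(top)[1]
  }
  per_mirna <- data.frame(mirna = rownames(tab), dominant = dominant,
                          reads = as.integer(rowSums(tab)), tie = tie,
                          stringsAsFactors = FALSE)
  distribution <- table(factor(dominant, levels = ISOMIR_CATEGORIES))
  distribution <- as.numeric(distribution) / nrow(per_mirna)
  names(distribution) <- ISOMIR_CATEGORIES
  list(per_mirna = per_mirna, distribution = distribution,
       variant_read_fraction = mean(calls$category != "CANONICAL"))
}
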