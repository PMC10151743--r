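#' Decompose an IGH junction into V / N1 / (D2-N0) / D / N2 / J parts
#'
#' Region inference when the upstream annotation pipeline did not provide
#' junction regions. The J part is the longest junction suffix (at least
#' 4 nt) occurring as an exact ungapped substring of the called J germline;
#' for IGH-VJ records the V part is analogously the longest junction prefix
#' (at least 4 nt) found in the called V germline. Within the remaining
#' middle, the D part is the best exact match of length `>= min_d_match`
#' against any catalog D. Ties are broken by match length (longest wins),
#' then by proximity to the J side, then by catalog D rank (smallest rank,
#' i.e. most D-cluster-proximal, wins). If a second disjoint D match of
#' length `>= min_d_match` exists 5' of the first, it becomes
#' `d2_part` (a D-D tandem) with the intervening nucleotides as `n0`.
#' Leftover middle nucleotides become `n1`/`n2`. With no D match the whole
#' middle is `n1` and `d_part` is empty.
#'
#' @param junction Junction nucleotide string (>= 6 nt, uppercase ACGT).
#' @param v_call V gene name or `NA` (IGH-DJ records).
#' @param j_call J gene name, present in the catalog.
#' @param catalog A [locus_catalog()].
#' @param min_d_match Minimum exact D match length (default 5 nt; shorter
#'   matches are frequent by chance in N regions).
#' @return A named list with `v_part`, `n1`, `d2_part`, `n0`, `d_part`,
#'   `n2`, `j_part`, `d_call` (the matched D gene or `NA`) and `d2_call`,
#'   or `NULL` when no J match is found (the record should be quarantined).
#' @export
decompose_junction <- function(junction, v_call, j_call, catalog,
                               min_d_match = 5) {
  junction <- toupper(junction)
  if (nchar(junction) < 6) stop("junction must be at least 6 nt", call. = FALSE)
  j_seq <- catalog_get(catalog, j_call, "J")$sequence

  j_len <- longest_suffix_in(junction, j_seq, min_len = 4)
  if (j_len == 0) return(NULL)
  n <- nchar(junction)
  j_part <- substr(junction, n - j_len + 1, n)

  v_part <- ""
  if (!is.na(v_call) && v_call != "") {
    v_seq <- catalog_get(catalog, v_call, "V")$sequence
    v_len <- longest_prefix_in(junction, v_seq, min_len = 4,
                               max_len = n - j_len)
    v_part <- substr(junction, 1, v_len)
  }
  middle <- substr(junction, nchar(v_part) + 1, n - j_len)

  d_cat <- catalog[catalog$segment_type == "D", , drop = FALSE]
  d_cat <- d_cat[order(d_cat$locus_rank), , drop = FALSE]
  hit <- best_d_match(middle, d_cat, min_d_match)
  if (is.null(hit)) {
    return(list(v_part = v_part, n1 = middle, d2_part = "", n0 = "",
                d_part = "", n2 = "", j_part = j_part,
                d_call = NA_character_, d2_call = NA_character_))
  }
  upstream <- substr(middle, 1, hit$start - 1)
  hit2 <- best_d_match(upstream, d_cat, min_d_match)
  if (is.null(hit2)) {
    list(v_part = v_part,
         n1 = upstream,
         d2_part = "", n0 = "",
         d_part = hit$match,
         n2 = substr(middle, hit$start + nchar(hit$match), nchar(middle)),
         j_part = j_part,
         d_call = hit$d_name, d2_call = NA_character_)
  } else {
    list(v_part = v_part,
         n1 = substr(upstream, 1, hit2$start - 1),
         d2_part = hit2$match,
         n0 = substr(upstream, hit2$start + nchar(hit2$match), nchar(upstream)),
         d_part = hit$match,
         n2 = substr(middle, hit$start + nchar(hit$match), nchar(middle)),
         j_part = j_part,
         d_call = hit$d_name, d2_call = hit2$d_name)
  }
}

longest_suffix_in <- function(x, subject, min_len = 4) {
  n <- nchar(x)
  from <- min(n, nchar(subject))
  if (from < min_len) return(0L)
  for (len in from:min_len) {
    if (grepl(substr(x, n - len + 1, n), subject, fixed = TRUE)) return(len)
  }
  0L
}

longest_prefix_in <- function(x, subject, min_len = 4, max_len = nchar(x)) {
  from <- min(max_len, nchar(subject))
  if (from < min_len) return(0L)
  for (len in from:min_len) {
    if (grepl(substr(x, 1, len), subject, fixed = TRUE)) return(len)
  }
  0L
}

# Best exact D match inside `middle`: longest, then J-proximal (largest
# start), then smallest catalog rank (d_cat must be rank-ordered).
best_d_match <- function(middle, d_cat, min_d_match) {
  m_len <- nchar(middle)
  if (m_len < min_d_match) return(NULL)
  subject <- paste(d_cat$sequence, collapse = "X")
  offsets <- cumsum(c(0, nchar(d_cat$sequence) + 1))[seq_len(nrow(d_cat))]
  max_l <- min(m_len, max(nchar(d_cat$sequence)))
  if (max_l < min_d_match) return(NULL)
  for (len in max_l:min_d_match) {
    for (start in (m_len - len + 1):1) {
      sub <- substr(middle, start, start + len - 1)
      pos <- regexpr(sub, subject, fixed = TRUE)
      if (pos > 0) {
        idx <- findInterval(as.integer(pos), offsets + 1)
        return(list(match = sub, start = start, d_name = d_cat$name[idx]))
      }
    }
  }
  NULL
}

#' Extract the DNJ-stem from a junction anatomy
#'
#' The DNJ-stem is the junction suffix formed by the last at-most-3
#' nucleotides of the D region, all N2 nucleotides between D and J, and the
#' entire J region. When no D is identifiable in a VJ rearrangement, the
#' last at-most-3 nucleotides of the single N region stand in for the D
#' contribution (`from_n_fallback`). This suffix is what remains stable
#' across ongoing D/V-to-DJ recombination and VH replacement, so it links
#' clonally related family members.
#'
#' @param anatomy A list or one-row data frame with `n1`, `d_part`, `n2`,
#'   `j_part` (as from [decompose_junction()]).
#' @return A list with `stem`, `d_contribution`, `n2_contribution`,
#'   `j_contribution` and `from_n_fallback`.
#' @export
extract_dnj_stem <- function(anatomy) {
  j_part <- anatomy$j_part
  if (is.null(j_part) || is.na(j_part) || j_part == "") {
    stop("anatomy must have a non-empty j_part", call. = FALSE)
  }
  d_part <- anatomy$d_part %||% ""
  n1 <- anatomy$n1 %||% ""
  n2 <- anatomy$n2 %||% ""
  if (is.na(d_part)) d_part <- ""
  if (is.na(n1)) n1 <- ""
  if (is.na(n2)) n2 <- ""
  if (d_part != "") {
    d_contribution <- str_tail(d_part, 3)
    from_n_fallback <- FALSE
  } else {
    d_contribution <- str_tail(n1, 3)
    from_n_fallback <- TRUE
  }
  list(
    stem = paste0(d_contribution, n2, j_part),
    d_contribution = d_contribution,
    n2_contribution = n2,
    j_contribution = j_part,
    from_n_fallback = from_n_fallback
  )
}
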