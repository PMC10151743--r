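#' Germline locus catalogs
#'
#' A locus catalog holds the germline IGHV/IGHD/IGHJ segments with their
#' position along the locus ("locus rank") and a functionality class. The
#' rank convention follows the physical gene order: V ranks increase with
#' distance from the D cluster, so the most D/J-proximal V gene (IGHV6-1 on
#' the real locus) has rank 1; D ranks increase toward the J cluster; J ranks
#' are in genomic order. Under this convention an incoming V segment lies
#' downstream of (i.e. was recombined onto a rearrangement carrying) an
#' original V exactly when its rank is larger.
#'
#' Allele suffixes (`*01` etc.) are stripped to the gene name for rank
#' lookups; sequences stay at the level they were supplied.
#'
#' @param segments A data frame with columns `name`, `segment_type`
#'   (one of `"V"`, `"D"`, `"J"`), `sequence` (uppercase ACGT),
#'   `locus_rank` (integer, unique within type) and `functionality`
#'   (one of `"functional"`, `"ORF"`, `"pseudogene"`).
#' @param version_tag Free-text provenance string.
#'
#' @return A tibble of class `locus_catalog` with one row per segment and an
#'   added `gene` column (allele-stripped name).
#' @export
locus_catalog <- function(segments, version_tag = "unversioned") {
  seg <- tibble::as_tibble(segments)
  required <- c("name", "segment_type", "sequence", "locus_rank", "functionality")
  missing <- setdiff(required, names(seg))
  if (length(missing) > 0) {
    stop("catalog is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  seg$sequence <- toupper(seg$sequence)
  bad_alpha <- !grepl("^[ACGT]+$", seg$sequence)
  if (any(bad_alpha)) {
    stop("non-ACGT characters in sequence(s) of: ",
         paste(seg$name[bad_alpha], collapse = ", "), call. = FALSE)
  }
  if (!all(seg$segment_type %in% c("V", "D", "J"))) {
    stop("segment_type must be one of V, D, J", call. = FALSE)
  }
  if (!all(seg$functionality %in% c("functional", "ORF", "pseudogene"))) {
    stop("functionality must be one of functional, ORF, pseudogene", call. = FALSE)
  }
  if (anyDuplicated(seg$name)) {
    stop("duplicate segment names: ",
         paste(unique(seg$name[duplicated(seg$name)]), collapse = ", "), call. = FALSE)
  }
  dup_rank <- seg |>
    dplyr::count(.data$segment_type, .data$locus_rank) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_rank) > 0) {
    stop("locus_rank must be unique within segment_type", call. = FALSE)
  }
  if (!all(c("V", "D", "J") %in% seg$segment_type)) {
    stop("catalog must contain at least one segment of each of V, D, J", call. = FALSE)
  }
  seg$gene <- strip_allele(seg$name)
  seg$locus_rank <- as.integer(seg$locus_rank)
  out <- seg[, c("name", "gene", "segment_type", "sequence", "locus_rank", "functionality")]
  attr(out, "version_tag") <- version_tag
  class(out) <- c("locus_catalog", class(out))
  out
}

#' Strip an allele suffix from a gene/allele identifier
#'
#' `"IGHV6-1*01"` becomes `"IGHV6-1"`; names without a `*` pass through.
#'
#' @param name Character vector of gene or allele identifiers.
#' @return Character vector of gene-level names.
#' @export
strip_allele <- function(name) {
  sub("\\*.*$", "", name)
}

#' Load a germline catalog from FASTA files and an order table
#'
#' Reads one FASTA file per segment type and a 3-column TSV (`name`, `rank`,
#' `functionality`) giving the locus order. Every FASTA record must appear
#' in the order table; records absent from it are rejected.
#'
#' @param v_fasta,d_fasta,j_fasta Paths to FASTA files of germline V, D and
#'   J segments.
#' @param order_table Path to a TSV with columns `name`, `rank`,
#'   `functionality` covering every FASTA record name.
#' @param version_tag Provenance string stored on the catalog.
#' @return A [locus_catalog()].
#' @export
load_catalog <- function(v_fasta, d_fasta, j_fasta, order_table,
                         version_tag = "user-supplied") {
  for (p in c(v_fasta, d_fasta, j_fasta, order_table)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  read_fa <- function(path, type) {
    ss <- Biostrings::readDNAStringSet(path)
    tibble::tibble(
      name = sub("\\s.*$", "", names(ss)),
      segment_type = type,
      sequence = toupper(as.character(ss))
    )
  }
  seqs <- dplyr::bind_rows(
    read_fa(v_fasta, "V"), read_fa(d_fasta, "D"), read_fa(j_fasta, "J")
  )
  ord <- readr::read_tsv(order_table, col_types = readr::cols(
    name = readr::col_character(),
    rank = readr::col_integer(),
    functionality = readr::col_character()
  ))
  absent <- setdiff(seqs$name, ord$name)
  if (length(absent) > 0) {
    stop("FASTA record(s) missing from the order table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  seg <- dplyr::inner_join(seqs, ord, by = "name") |>
    dplyr::rename(locus_rank = "rank")
  locus_catalog(seg, version_tag = version_tag)
}

catalog_get <- function(catalog, name, type = NULL) {
  hit <- catalog[catalog$name == name | catalog$gene == strip_allele(name), , drop = FALSE]
  if (!is.null(type)) hit <- hit[hit$segment_type == type, , drop = FALSE]
  if (nrow(hit) == 0) {
    stop("segment not found in catalog: ", name, call. = FALSE)
  }
  hit[1, , drop = FALSE]
}

#' Is one V gene downstream of another along the locus?
#'
#' "Downstream" means farther from the D cluster: the direction in which an
#' incoming V segment must lie relative to the V it replaces during VH
#' replacement, because replacement deletes the intervening germline.
#'
#' @param catalog A [locus_catalog()].
#' @param incoming,original V gene (or allele) names present in the catalog.
#' @return `TRUE` iff `incoming` has a strictly larger locus rank.
#' @export
is_downstream <- function(catalog, incoming, original) {
  a <- catalog_get(catalog, incoming, "V")
  b <- catalog_get(catalog, original, "V")
  a$locus_rank > b$locus_rank
}

#' Extract the 3' tail of a germline V segment
#'
#' VH replacement can leave a remnant of up to five base pairs of the
#' replaced V gene's 3' end inside the new junction; this helper returns
#' the candidate remnant of length `k`.
#'
#' @param catalog A [locus_catalog()].
#' @param v_name V gene (or allele) name in the catalog.
#' @param k Tail length, between 1 and 5.
#' @return The last `k` nucleotides of the germline V sequence.
#' @export
v_three_prime_tail <- function(catalog, v_name, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k > 5) {
    stop("k must be a single integer in [1, 5]", call. = FALSE)
  }
  seq <- catalog_get(catalog, v_name, "V")$sequence
  substr(seq, nchar(seq) - k + 1, nchar(seq))
}

#' Bundled synthetic toy IGH locus
#'
#' A small synthetic germline catalog (10 V, 6 D, 3 J) used by the simulator
#' and the test suite. Sequences are random but fixed, chosen so that no two
#' D segments share a 5-mer and no D 5-mer occurs in any V or J segment,
#' which makes D assignment in simulated junctions unambiguous at the
#' default matching threshold. Names follow the real locus ordering
#' convention (IGHV6-1 is the most D-proximal V, rank 1); they are synthetic
#' stand-ins, not IMGT sequences.
#'
#' @return A [locus_catalog()].
#' @export
toy_locus <- function() {
  v_seq <- c(
    "TACCGTTTCATGCCGGTAGTACCATTTAATAGAAGGGCAGAGAAAGAC",
    "AGTCTGGTTTCAATCCTAGACGTGACCTTCACCGTAGCGAGATGCGCC",
    "GAAAGAATCTAAGCATACACCAGTAGGGACTGCGGCAAACTTACTCGG",
    "GACCCGGTACGATATTCGCCTATCAACTTTAGAACTGTTGACTATAGC",
    "GTCTCATTTTTTGGGGCTTCACTGCAGGGGCGCCCAATGAACTGAGTT",
    "CCTATGATCTATACATGCGATATCTGGCTCGCTTGCGTCGAAGCCAGG",
    "TCAGGCTCTCCGGCAGGGGAAGTTGGGCGCCGAGTGATTATTGAAATC",
    "GGAATGCGCCGCGTGCTCAAATGCAACCCTCCGAATGCATTTGGGAAA",
    "GGGAGATTTTACTTCATACACGGTCTGCGAATGGTCTGGTAATTGGTC",
    "AATACGTGACCTACGAGGTGCGCGGAGATTACGCTAGGGCCTAGACCC"
  )
  d_seq <- c(
    "ATCGATGTATAAGT",
    "GGACAAGCTGCCTTGG",
    "CAGTCAAGGATG",
    "TTTTCCTCGTCCCCC",
    "CAAAACCACAATT",
    "ATTAACCTCTGTACTG"
  )
  j_seq <- c(
    "AAACATTTCGCTTGAAGTGTGGGAGC",
    "GTCTTAAGCCCCTGACGACTTTTGGA",
    "GATCCGGGGCATCCAAAGAGGAATGC"
  )
  v_names <- c("IGHV6-1", "IGHV1-2", "IGHV1-3", "IGHV4-4", "IGHV2-5",
               "IGHV3-7", "IGHV1-8", "IGHV3-9", "IGHV3-11", "IGHV3-74")
  d_names <- c("IGHD1-1", "IGHD2-2", "IGHD3-3", "IGHD4-4", "IGHD5-5", "IGHD6-6")
  j_names <- c("IGHJ4", "IGHJ5", "IGHJ6")
  v_fun <- rep("functional", 10)
  v_fun[7] <- "ORF"
  v_fun[8] <- "pseudogene"
  segments <- tibble::tibble(
    name = c(v_names, d_names, j_names),
    segment_type = rep(c("V", "D", "J"), times = c(10, 6, 3)),
    sequence = c(v_seq, d_seq, j_seq),
    locus_rank = c(1:10, 1:6, 1:3),
    functionality = c(v_fun, rep("functional", 9))
  )
  locus_catalog(segments, version_tag = "dnjstem-toy-locus-1")
}
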