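# Shared fixtures, all built in code.

toy <- toy_locus()

# A tiny hand-built catalog whose sequences embed the worked examples used
# across the junction tests.
mini_catalog <- function() {
  locus_catalog(tibble::tibble(
    name = c("Vtoy1", "Vtoy2", "Dtoy1", "Dtoy2", "Jtoy1"),
    segment_type = c("V", "V", "D", "D", "J"),
    sequence = c(
      "CCATTGTGTGCGAGAG",      # ends with the example junction prefix
      "TTGGAAACGATT",          # 3' tail ACGATT used in footprint examples
      "GGGACTACTTC",           # contains GACTAC
      "CCAGTAGTCAT",           # contains AGTAGT
      "TTTGACTACTGGGGCCAA"     # starts with the example J part
    ),
    locus_rank = c(1, 2, 1, 2, 1),
    functionality = "functional"
  ))
}

# Minimal sample around an explicit clonotype table.
make_sample <- function(clonotypes, library = "IGH-VJ", qc_reads = 0,
                        qc_cells = 0, sample_id = "S1", patient_id = "PT1") {
  airr_sample(clonotypes, sample_id = sample_id, patient_id = patient_id,
              library = library, qc_reads = qc_reads,
              qc_cell_equivalents = qc_cells)
}

# A clonotype row with explicit anatomy; junction is the concatenation.
anat_row <- function(id, v_call = "IGHV6-1", d_call = "IGHD1-1",
                     j_call = "IGHJ4", v_part = "TGTGCG", n1 = "",
                     d2_part = "", n0 = "", d_part = "ATCGATGTATAAGT",
                     n2 = "", j_part = "AAACATTTCGCTTGAAGTGTGGGAGC",
                     read_count = 100) {
  tibble::tibble(
    clonotype_id = id, v_call = v_call, d_call = d_call,
    d2_call = NA_character_, j_call = j_call,
    v_part = v_part, n1 = n1, d2_part = d2_part, n0 = n0,
    d_part = d_part, n2 = n2, j_part = j_part,
    junction = paste0(v_part, n1, d2_part, n0, d_part, n2, j_part),
    read_count = read_count
  )
}

# Write a small AIRR TSV to a temp file, return the path.
write_airr_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

default_meta <- function(library = "IGH-VJ", qc_cells = 100) {
  list(sample_id = "S1", patient_id = "PT1", compartment = "BM",
       timepoint_label = "day0", library = library,
       qc_cell_equivalents_input = qc_cells)
}

# Union-find partition over pairwise stem equality: the brute-force
# grouping oracle.
brute_force_partition <- function(stems) {
  n <- length(stems)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stems[i] == stems[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}
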