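#' Analyze one sample library end to end
#'
#' Runs the full per-library chain: anatomy/stem annotation, stem-family
#' grouping, noise filtering, the evolution consensus call and marker
#' calling. Rooting and mechanism classification need both libraries; use
#' [analyze_sample_pair()] for those.
#'
#' @param sample An [airr_sample()].
#' @param catalog A [locus_catalog()] (used only where anatomy is not
#'   pre-filled).
#' @param npolicy,epolicy,mpolicy Policies; see [noise_policy()],
#'   [evolution_policy()], [marker_policy()].
#' @param min_d_match Minimum exact D match for junction decomposition.
#' @return An object of class `stem_analysis`: a list with the annotated
#'   `sample` and the `families` tibble.
#' @export
analyze_sample <- function(sample, catalog = NULL,
                           npolicy = noise_policy(),
                           epolicy = evolution_policy(),
                           mpolicy = marker_policy(),
                           min_d_match = 5) {
  sample <- annotate_stems(sample, catalog, min_d_match = min_d_match)
  families <- group_by_stem(sample)
  families <- call_stem_evolution(families, sample, npolicy, epolicy)
  families <- call_markers(families, sample, mpolicy)
  structure(list(sample = sample, families = families), class = "stem_analysis")
}

#' Analyze a sample's IGH-VJ and IGH-DJ libraries together
#'
#' Analyzes each library independently (evolution is called per library, so
#' DJ-only evolution is caught), flags rooted stems across the libraries,
#' and classifies the mechanism of every evolving family.
#'
#' @param vj,dj [airr_sample()]s of the two libraries of one sample.
#' @param catalog A [locus_catalog()].
#' @param npolicy,epolicy,mpolicy,mechpolicy Policies.
#' @param min_d_match Minimum exact D match for junction decomposition.
#' @return A list of class `stem_analysis_pair` with elements `vj` and
#'   `dj` (each a `stem_analysis` whose families carry `rooted` and
#'   mechanism columns).
#' @export
analyze_sample_pair <- function(vj, dj, catalog = NULL,
                                npolicy = noise_policy(),
                                epolicy = evolution_policy(),
                                mpolicy = marker_policy(),
                                mechpolicy = mechanism_policy(),
                                min_d_match = 5) {
  a_vj <- analyze_sample(vj, catalog, npolicy, epolicy, mpolicy, min_d_match)
  a_dj <- analyze_sample(dj, catalog, npolicy, epolicy, mpolicy, min_d_match)
  rooted <- detect_root(a_vj$families, a_dj$families)
  a_vj$families <- rooted$vj
  a_dj$families <- rooted$dj
  a_vj$families <- classify_mechanisms(a_vj$families, catalog, mechpolicy,
                                       dj_families = a_dj$families)
  a_dj$families <- classify_mechanisms(a_dj$families, catalog, mechpolicy,
                                       dj_families = NULL)
  structure(list(vj = a_vj, dj = a_dj), class = "stem_analysis_pair")
}

#' @export
print.stem_analysis <- function(x, ...) {
  f <- x$families
  cat(sprintf(
    "<stem_analysis> %s [%s]: %d families (%d evolving, %d markers)\n",
    x$sample$sample_id, x$sample$library, nrow(f),
    sum(f$call == "evolving"), sum(f$is_marker)
  ))
  invisible(x)
}

#' Turn an analysis object into a tidy tibble
#'
#' Broom-style generics: `tidy()` returns the per-unit result table,
#' `glance()` a one-row summary.
#'
#' @param x An analysis object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Tidy a stem analysis into a flat family table
#'
#' @param x A `stem_analysis`.
#' @param ... Unused.
#' @return A tibble with one row per stem family and the scalar family
#'   columns (list-columns dropped).
#' @export
tidy.stem_analysis <- function(x, ...) {
  f <- x$families
  keep <- !vapply(f, is.list, TRUE)
  f <- f[, keep, drop = FALSE]
  if ("criteria_fired" %in% names(x$families)) {
    f$criteria_fired <- purrr::map_chr(
      x$families$criteria_fired, ~ paste(.x, collapse = "+"))
  }
  tibble::as_tibble(f)
}

#' One-row summary of a stem analysis
#'
#' @param x A `stem_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: sample identity, usable reads, family counts,
#'   evolving and marker counts.
#' @export
glance.stem_analysis <- function(x, ...) {
  f <- x$families
  tibble::tibble(
    sample_id = x$sample$sample_id,
    library = x$sample$library,
    usable_reads = x$sample$usable_reads,
    n_clonotypes = nrow(x$sample$clonotypes),
    n_families = nrow(f),
    n_evolving = sum(f$call == "evolving"),
    n_markers = sum(f$is_marker),
    n_conventionally_missed = sum(f$is_marker & f$would_conventional_miss)
  )
}
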