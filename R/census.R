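# Cross-database content census: per-class instance counts and
# percentage-of-maximum normalization.

CENSUS_CLASSES <- c("BiochemicalReaction", "PathwayStep", "Pathway",
                    "Interaction", "SmallMolecule", "Protein", "Dna", "Rna")

#' Count instances of the eight census classes in a graph
#'
#' Tallies `rdf:type` declarations for the eight BioPAX classes used to
#' compare database exports: BiochemicalReaction, PathwayStep, Pathway,
#' Interaction, SmallMolecule, Protein, Dna and Rna. `Interaction` is
#' counted as direct instances of the Interaction class only — its
#' subclasses (BiochemicalReaction, Catalysis, ...) are separate axes of the
#' comparison, and including them would double-count. Set
#' `interaction_subclasses = TRUE` to count the subclass closure instead.
#'
#' @param graph A [biopax_graph()].
#' @param label Source label for the document (e.g. `"Reactome v90"`).
#' @param interaction_subclasses Count Interaction with its subclass
#'   closure? Default `FALSE`.
#' @return A tibble of class `biopax_census` with columns `source`, `class`,
#'   `n` — one row per census class.
#' @examples
#' count_classes(rna_pol2_fixture(), "worked example")
#' @export
count_classes <- function(graph, label = "graph",
                          interaction_subclasses = FALSE) {
  n <- vapply(CENSUS_CLASSES, function(cl) {
    length(instances_of(graph, cl,
                        include_subclasses =
                          cl == "Interaction" && interaction_subclasses))
  }, integer(1))
  out <- tibble::tibble(source = label, class = CENSUS_CLASSES, n = unname(n))
  class(out) <- c("biopax_census", class(out))
  out
}

#' Normalize censuses as percentage of the per-class maximum
#'
#' For each class, counts are rescaled so that the source with the largest
#' count scores 100 and the others score proportionally; a class with zero
#' counts everywhere scores 0 for every source (keeping all values finite
#' for plotting).
#'
#' @param censuses A single census tibble (possibly covering several
#'   sources, e.g. after `dplyr::bind_rows()`) or a list of census tibbles
#'   from [count_classes()].
#' @return A tibble of class `biopax_census` with columns `source`, `class`,
#'   `n`, `pct` where `pct` is in `[0, 100]`.
#' @examples
#' a <- count_classes(rna_pol2_fixture(), "A")
#' normalize_census(list(a, a))
#' @export
normalize_census <- function(censuses) {
  if (is.data.frame(censuses)) censuses <- list(censuses)
  if (length(censuses) == 0) {
    abort("normalize_census() needs at least one census")
  }
  combined <- dplyr::bind_rows(censuses)
  stopifnot(all(c("source", "class", "n") %in% names(combined)))
  out <- combined |>
    dplyr::group_by(.data$class) |>
    dplyr::mutate(pct = if (max(.data$n) == 0) 0
                  else 100 * .data$n / max(.data$n)) |>
    dplyr::ungroup()
  out$class <- factor(out$class, levels = CENSUS_CLASSES)
  out <- dplyr::arrange(out, .data$source, .data$class)
  out$class <- as.character(out$class)
  class(out) <- c("biopax_census", class(out))
  out
}

#' Write a census report as TSV
#'
#' One row per source; for every census class a raw-count column (`<class>`)
#' and, when the census has been normalized, a percentage column
#' (`<class>_pct`) side by side.
#'
#' @param census A (possibly normalized) census tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_census_report <- function(census, path) {
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(census),
    id_cols = "source", names_from = "class",
    values_from = dplyr::any_of(c("n", "pct")),
    names_glue = if ("pct" %in% names(census)) {
      "{class}{ifelse(.value == 'pct', '_pct', '')}"
    } else "{class}"
  )
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
glance.biopax_census <- function(x, ...) {
  tibble::tibble(
    n_sources = length(unique(x$source)),
    n_classes = length(unique(x$class)),
    total_instances = sum(x$n)
  )
}
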