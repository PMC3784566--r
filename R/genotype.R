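#' @keywords internal
mutation_categories <- c(
  "spacer_deletion", "spacer_point", "is_insertion", "frameshift",
  "nonsense", "missense", "locus_deletion"
)

# en dash / minus sign to ASCII hyphen; collapse stray whitespace
normalize_genotype <- function(x) {
  x <- gsub("–|−", "-", x)
  gsub("\\s+", " ", trimws(x))
}

parse_one_genotype <- function(x) {
  g <- normalize_genotype(x)
  empty <- tibble(
    genotype = x, category = NA_character_, gene = NA_character_,
    position = NA_integer_, element = NA_character_,
    orientation = NA_character_, spacers = NA_character_,
    nt_change = NA_character_, aa_change = NA_character_,
    del_start = NA_integer_, del_end = NA_integer_, span = NA_integer_,
    mediator = NA_character_
  )
  # spacer deletion: "Δspc1", "Δspc1,2,3"
  m <- stringr::str_match(g, "^Δspc([0-9]+(?:,[0-9]+)*)$")
  if (!is.na(m[1, 1])) {
    return(mutate(empty, category = "spacer_deletion", spacers = m[1, 2]))
  }
  # locus deletion: "Δ2387081-2520252 (IS256)"
  m <- stringr::str_match(g, "^Δ([0-9]+)-([0-9]+)(?: \\(([^)]+)\\))?$")
  if (!is.na(m[1, 1])) {
    ds <- as.integer(m[1, 2])
    de <- as.integer(m[1, 3])
    if (ds >= de) {
      abort(paste0("locus deletion with start >= end: '", x, "'"))
    }
    return(mutate(empty,
      category = "locus_deletion", del_start = ds, del_end = de,
      span = de - ds + 1L, mediator = m[1, 4]
    ))
  }
  # IS-element insertion: "csm6(617)::IS256-d"
  m <- stringr::str_match(
    g, "^([A-Za-z][A-Za-z0-9]*)\\(([0-9]+)\\)::([A-Za-z]+[0-9]+)-(d|i)$"
  )
  if (!is.na(m[1, 1])) {
    return(mutate(empty,
      category = "is_insertion", gene = m[1, 2],
      position = as.integer(m[1, 3]), element = m[1, 4],
      orientation = if (m[1, 5] == "d") "direct" else "inverted"
    ))
  }
  # single-nucleotide deletion: "cas10(ΔA979). Frameshift" / "spc1(ΔA1)";
  # frameshift in a cas/csm gene, a spacer change in a spacer
  m <- stringr::str_match(
    g, "^([A-Za-z][A-Za-z0-9]*)\\(Δ([ACGT])([0-9]+)\\)\\.?( Frameshift)?$"
  )
  if (!is.na(m[1, 1])) {
    gname <- m[1, 2]
    cat <- if (stringr::str_starts(gname, "spc")) "spacer_point" else "frameshift"
    return(mutate(empty,
      category = cat, gene = gname, position = as.integer(m[1, 4]),
      nt_change = paste0("Δ", m[1, 3], m[1, 4])
    ))
  }
  # substitution: "cas10(C1411T; Q471Stop)" nonsense, "csm4(G566T; G189V)" missense
  m <- stringr::str_match(
    g,
    "^([A-Za-z][A-Za-z0-9]*)\\(([ACGT][0-9]+[ACGT]); ([A-Z][0-9]+(?:[A-Z][a-z]*|Stop))\\)$"
  )
  if (!is.na(m[1, 1])) {
    aa <- m[1, 4]
    cat <- if (stringr::str_ends(aa, "Stop")) "nonsense" else "missense"
    pos <- as.integer(stringr::str_match(m[1, 3], "[0-9]+")[1, 1])
    return(mutate(empty,
      category = cat, gene = m[1, 2], position = pos,
      nt_change = m[1, 3], aa_change = aa
    ))
  }
  abort(paste0("unparseable genotype string: '", x, "'"))
}

#' Parse escape-genotype notation into structured mutation calls
#'
#' Understands the compact notation used to report the genotypes of
#' transconjugants that escaped CRISPR immunity:
#' * `Δspc1,2` -- deletion of spacers 1 and 2 from the repeat-spacer array;
#' * `Δ2387081–2520252 (IS256)` -- deletion of the chromosomal segment
#'   between the 1-based inclusive coordinates, mediated by the element in
#'   parentheses (span = end - start + 1);
#' * `csm6(617)::IS256-d` -- IS-element insertion at nucleotide 617 of the
#'   gene, transposase in direct (`-d`) or inverted (`-i`) orientation;
#' * `cas10(ΔA979). Frameshift` -- single-adenine deletion causing a
#'   frameshift; the same form in a spacer (`spc1(ΔA1)`) is a spacer point
#'   change;
#' * `cas10(C1411T; Q471Stop)` -- nucleotide substitution with its protein
#'   consequence, classified nonsense when the change creates a stop codon
#'   and missense otherwise.
#'
#' En dashes and Unicode minus signs are accepted interchangeably with
#' hyphens in coordinate ranges. Unparseable strings raise an error naming
#' the offending string; nothing is skipped silently.
#'
#' @param genotype character vector of genotype strings.
#' @return tibble with one row per string: `genotype`, `category` (one of
#'   spacer_deletion, spacer_point, is_insertion, frameshift, nonsense,
#'   missense, locus_deletion) and the category-specific fields `gene`,
#'   `position`, `element`, `orientation`, `spacers`, `nt_change`,
#'   `aa_change`, `del_start`, `del_end`, `span`, `mediator`.
#' @examples
#' parse_genotype(c("Δspc1,2", "csm6(617)::IS256-d"))
#' @export
parse_genotype <- function(genotype) {
  if (length(genotype) == 0) {
    return(parse_one_genotype("Δspc1")[0, ])
  }
  if (any(is.na(genotype) | !nzchar(genotype))) {
    abort("genotype strings must be non-empty")
  }
  map_dfr(genotype, parse_one_genotype)
}

#' Serialize structured mutation calls back to genotype notation
#'
#' Inverse of [parse_genotype()]; `parse_genotype(serialize_genotype(x))`
#' reproduces `x` for every parseable call.
#'
#' @param calls tibble of mutation calls from [parse_genotype()].
#' @return character vector of genotype strings.
#' @export
serialize_genotype <- function(calls) {
  vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    switch(r$category,
      spacer_deletion = paste0("Δspc", r$spacers),
      locus_deletion = paste0(
        "Δ", r$del_start, "–", r$del_end,
        if (!is.na(r$mediator)) paste0(" (", r$mediator, ")") else ""
      ),
      is_insertion = paste0(
        r$gene, "(", r$position, ")::", r$element, "-",
        if (r$orientation == "direct") "d" else "i"
      ),
      frameshift = paste0(r$gene, "(", r$nt_change, "). Frameshift"),
      spacer_point = paste0(r$gene, "(", r$nt_change, ")"),
      nonsense = ,
      missense = paste0(r$gene, "(", r$nt_change, "; ", r$aa_change, ")"),
      abort(paste0("cannot serialize category '", r$category, "'"))
    )
  }, character(1))
}

#' Tally the spectrum of CRISPR-escape mutations
#'
#' Counts isolates per mutation category (each isolate carries one genotype
#' call and counts once) and the corresponding proportions over all
#' records.
#'
#' @param records data frame with columns `isolate_id` and
#'   `genotype_string` (see [read_genotypes()]).
#' @return tibble with one row per category (all seven categories always
#'   present, zero-filled): `category`, `n`, `proportion`.
#' @export
tally_spectrum <- function(records) {
  assert_columns(records, c("isolate_id", "genotype_string"))
  base <- tibble(category = mutation_categories, n0 = 0L)
  if (nrow(records) == 0) {
    return(tibble(category = mutation_categories, n = 0L, proportion = 0))
  }
  calls <- parse_genotype(records$genotype_string)
  counts <- calls |>
    dplyr::count(.data$category)
  base |>
    left_join(counts, by = "category") |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      proportion = .data$n / nrow(records)
    ) |>
    select("category", "n", "proportion")
}

#' Chromosomal deletion spans among escape genotypes
#'
#' Extracts every locus-deletion call and its inclusive span in
#' nucleotides. Distinct deletion variants are keyed by their coordinate
#' pair, so isolates sharing breakpoints count as one variant.
#'
#' @inheritParams tally_spectrum
#' @return tibble with columns `isolate_id`, `del_start`, `del_end`,
#'   `span`, `mediator`, one row per deletion-bearing isolate.
#' @seealso [summarize_spans()] for the variant count and span range.
#' @export
deletion_spans <- function(records) {
  assert_columns(records, c("isolate_id", "genotype_string"))
  calls <- parse_genotype(records$genotype_string)
  out <- tibble(
    isolate_id = records$isolate_id,
    category = calls$category,
    del_start = calls$del_start, del_end = calls$del_end,
    span = calls$span, mediator = calls$mediator
  )
  out |>
    filter(.data$category == "locus_deletion") |>
    select(-"category")
}

#' @rdname deletion_spans
#' @param spans output of [deletion_spans()].
#' @return `summarize_spans()`: one-row tibble with `n_deletions`,
#'   `n_variants` (distinct coordinate pairs), `min_span`, `max_span`.
#' @export
summarize_spans <- function(spans) {
  assert_columns(spans, c("del_start", "del_end", "span"))
  tibble(
    n_deletions = nrow(spans),
    n_variants = nrow(distinct(spans, .data$del_start, .data$del_end)),
    min_span = if (nrow(spans)) min(spans$span) else NA_integer_,
    max_span = if (nrow(spans)) max(spans$span) else NA_integer_
  )
}

#' Deleted fraction of the genome
#'
#' Expresses a deletion span as a percentage of the genome. The default
#' genome length is the 2,616,530-nt *S. epidermidis* RP62a chromosome;
#' including the large resident plasmid gives about 2.64 Mb, and both
#' conventions appear in published percentage figures, so the length is
#' configurable.
#'
#' @param span deletion span in nucleotides (> 0).
#' @param genome_length genome length in nucleotides.
#' @return percentage, `100 * span / genome_length` (exact; round to one
#'   decimal for presentation).
#' @examples
#' genome_fraction(65712) # about 2.5
#' @export
genome_fraction <- function(span, genome_length = 2616530) {
  if (any(span <= 0)) abort("`span` must be > 0")
  if (any(span > genome_length)) {
    abort("`span` cannot exceed `genome_length`")
  }
  100 * span / genome_length
}
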