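#' Paths to packaged example tables
#'
#' The package ships plain-text transcriptions of the published study
#' tables: `table1_matings.tsv` (filter-mating densities and
#' transconjugant yields), `table3_fluctuation.tsv` (fluctuation-experiment
#' transconjugant counts under both designs) and `table2_genotypes.csv`
#' (escape-genotype strings for every analyzed transconjugant).
#'
#' @param file fixture file name; with no argument, lists available files.
#' @return full path to the file, or a character vector of file names.
#' @examples
#' crisprflux_example()
#' read_matings(crisprflux_example("table1_matings.tsv"))
#' @export
crisprflux_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "crisprflux")))
  }
  path <- system.file("extdata", file, package = "crisprflux")
  if (!nzchar(path)) abort(paste0("no packaged file '", file, "'"))
  path
}

# read a delimited file and validate against a named vector of column types
# ("d" double, "i" integer, "c" character, "l" logical); extra columns pass
# through, missing or malformed ones raise an error naming the row/column
read_checked <- function(path, schema, delim = "\t",
                         call = rlang::caller_env()) {
  if (!file.exists(path)) {
    abort(paste0("file not found: '", path, "'"), call = call)
  }
  tab <- tryCatch(
    readr::read_delim(
      path,
      delim = delim, col_types = readr::cols(.default = readr::col_character()),
      trim_ws = TRUE, progress = FALSE
    ),
    error = function(e) {
      abort(paste0("cannot read '", path, "': ", conditionMessage(e)),
        call = call
      )
    }
  )
  missing <- setdiff(names(schema), names(tab))
  if (length(missing) > 0) {
    abort(
      paste0(
        "'", path, "' is missing required column(s): ",
        paste(missing, collapse = ", ")
      ),
      call = call
    )
  }
  for (col in names(schema)) {
    raw <- tab[[col]]
    parsed <- switch(schema[[col]],
      d = suppressWarnings(as.numeric(raw)),
      i = suppressWarnings(as.integer(raw)),
      l = as.logical(raw),
      c = raw
    )
    bad <- which(!is.na(raw) & is.na(parsed))
    if (length(bad) > 0) {
      abort(
        paste0(
          "'", path, "' column '", col, "', row ", bad[1],
          ": cannot parse value '", raw[bad[1]], "'"
        ),
        call = call
      )
    }
    tab[[col]] <- parsed
  }
  tab
}

#' Read and write mating count tables
#'
#' Tab-separated table with header columns `donor_plasmid`,
#' `recipient_strain`, `D`, `R`, `T`, `immune`; densities in cfu/ml,
#' scientific notation accepted, `immune` logical (TRUE when the
#' recipient's CRISPR-Cas system targets the donor plasmid).
#'
#' @param path file path.
#' @return `read_matings()`: validated tibble. `write_matings()`: `path`,
#'   invisibly.
#' @export
read_matings <- function(path) {
  read_checked(path, c(
    donor_plasmid = "c", recipient_strain = "c",
    D = "d", R = "d", T = "d", immune = "l"
  ))
}

#' @rdname read_matings
#' @param matings data frame in the same schema.
#' @export
write_matings <- function(matings, path) {
  assert_columns(matings, c("donor_plasmid", "recipient_strain", "D", "R", "T", "immune"))
  readr::write_tsv(matings, path)
  invisible(path)
}

#' Read and write fluctuation-experiment count tables
#'
#' Tab-separated table with columns `replicate`, `design`
#' (`independent_cultures` or `aliquots`), `transconjugants` and optional
#' `recipients` (cfu/ml).
#'
#' @param path file path.
#' @return `read_fluctuation_counts()`: validated tibble.
#'   `write_fluctuation_counts()`: `path`, invisibly.
#' @export
read_fluctuation_counts <- function(path) {
  read_checked(path, c(replicate = "i", design = "c", transconjugants = "d"))
}

#' @rdname read_fluctuation_counts
#' @param counts data frame in the same schema.
#' @export
write_fluctuation_counts <- function(counts, path) {
  assert_columns(counts, c("replicate", "design", "transconjugants"))
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read and write escape-genotype tables
#'
#' Comma-separated table with columns `isolate_id`, `genotype_string`,
#' `batch`. Genotype strings may contain commas (spacer lists), so fields
#' are quoted; Unicode deltas and en dashes are preserved as written.
#'
#' @param path file path.
#' @return `read_genotypes()`: validated tibble. `write_genotypes()`:
#'   `path`, invisibly.
#' @export
read_genotypes <- function(path) {
  read_checked(
    path, c(isolate_id = "c", genotype_string = "c", batch = "c"),
    delim = ","
  )
}

#' @rdname read_genotypes
#' @param records data frame in the same schema.
#' @export
write_genotypes <- function(records, path) {
  assert_columns(records, c("isolate_id", "genotype_string", "batch"))
  readr::write_csv(records, path)
  invisible(path)
}

#' Read and write competition trajectories
#'
#' Tab-separated table with either columns `transfer`, `q` or columns
#' `transfer`, `total`, `plasmid_bearing` (colony counts, from which
#' `q = plasmid_bearing / total`).
#'
#' @param path file path.
#' @return `read_trajectory()`: validated tibble with a `q` column.
#'   `write_trajectory()`: `path`, invisibly.
#' @export
read_trajectory <- function(path) {
  header <- names(readr::read_tsv(path,
    n_max = 0, col_types = readr::cols(), progress = FALSE
  ))
  if ("q" %in% header) {
    read_checked(path, c(transfer = "i", q = "d"))
  } else {
    tab <- read_checked(path, c(transfer = "i", total = "d", plasmid_bearing = "d"))
    mutate(tab, q = .data$plasmid_bearing / .data$total)
  }
}

#' @rdname read_trajectory
#' @param traj data frame in one of the two schemas.
#' @export
write_trajectory <- function(traj, path) {
  assert_columns(traj, "transfer")
  readr::write_tsv(traj, path)
  invisible(path)
}

#' Write a simulated trajectory or ensemble to TSV
#'
#' Trajectories are written as `time, R_res, CP, CN, D1, D2, T1, T2`;
#' ensembles as per-run final states (`run`, populations) followed by the
#' per-population summary in a second file `<path>.summary.tsv`.
#'
#' @param x a `plasmid_trajectory` or `plasmid_ensemble`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_dynamics <- function(x, path) {
  if (inherits(x, "plasmid_ensemble")) {
    readr::write_tsv(x$final, path)
    readr::write_tsv(x$summary, paste0(path, ".summary.tsv"))
  } else {
    readr::write_tsv(as_tibble(x), path)
  }
  invisible(path)
}
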