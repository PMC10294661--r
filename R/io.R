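## Shared format IO and pipeline configuration.

#' Read a FASTA file of named sequences
#'
#' Sequences are upper-cased; duplicate record names are an error. CRLF line
#' endings and arbitrary line wrapping are tolerated.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(setNames(character(0), character(0)))
  names(set) <- sub("\\s.*$", "", names(set)) # first token of the header
  if (anyDuplicated(names(set)) > 0L) {
    abort(sprintf(
      "Duplicate sequence name(s) in '%s': %s", path,
      paste(unique(names(set)[duplicated(names(set))]), collapse = ", ")
    ))
  }
  setNames(toupper(as.character(set)), names(set))
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (!is.character(seqs) || is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("`seqs` must be a named character vector.")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

# Columns serialised as comma-joined strings in TSV output.
serialize_list_cols <- function(data) {
  for (col in names(data)) {
    if (is.list(data[[col]])) {
      data[[col]] <- vapply(
        data[[col]],
        function(x) paste(as.character(x %||% character(0)), collapse = ","),
        character(1)
      )
    }
  }
  data
}

#' Write a record table as TSV
#'
#' List-columns (such as a design table's `intact_repeats`) are serialised
#' as comma-joined strings; [read_tsv()] restores them when asked.
#'
#' @param records A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  records <- serialize_list_cols(as_tibble(records))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV record table
#'
#' @param path Input path.
#' @param list_cols Column names to split back into list-columns on commas
#'   (e.g. `"intact_repeats"` for design tables).
#' @return A tibble.
#' @export
read_tsv <- function(path, list_cols = character(0)) {
  out <- as_tibble(utils::read.delim(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE))
  for (col in intersect(list_cols, names(out))) {
    out[[col]] <- lapply(out[[col]], function(x) {
      if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1L]]
    })
  }
  out
}

PIPELINE_DEFAULTS <- list(
  window = 30L,        # nt, ChIP enrichment window
  step = 15L,          # nt, window step
  background = 3000L,  # nt, background window
  oligo_len = 40L,     # nt, ReDCaT duplex length limit
  lfc = 1,             # volcano |log2FC| threshold (strict)
  p = 0.01,            # volcano P threshold (inclusive)
  loss_fraction = 0.2, # footprint binding-loss fraction
  seed = NULL          # global seed; NULL leaves the RNG alone
)

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration, fills defaults
#' (window 30, step 15, background 3000, oligo_len 40, lfc 1, p 0.01,
#' loss_fraction 0.2), rejects unknown keys by name, and type-checks every
#' value. The returned object carries a provenance record (configuration
#' hash, seed, package version) for reproducibility.
#'
#' @param path Path to a YAML/JSON file; an empty file yields all defaults.
#' @return A named list of class `pipeline_config` with attribute
#'   `provenance`.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) abort(sprintf("'%s' must contain a key-value mapping.", path))
  unknown <- setdiff(names(user), names(PIPELINE_DEFAULTS))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(PIPELINE_DEFAULTS, user)
  for (key in c("window", "step", "background", "oligo_len")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v != round(v)) {
      abort(sprintf("Configuration key `%s` must be a positive integer.", key))
    }
    cfg[[key]] <- as.integer(v)
  }
  for (key in c("lfc", "p", "loss_fraction")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("Configuration key `%s` must be a non-negative number.", key))
    }
  }
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || cfg$seed != round(cfg$seed)) {
      abort("Configuration key `seed` must be a single integer.")
    }
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(
    cfg,
    provenance = list(
      config_hash = hash(cfg),
      seed = cfg$seed,
      package_version = as.character(utils::packageVersion("regbind")),
      loaded_from = normalizePath(path, mustWork = FALSE)
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<pipeline_config>\n")
  for (key in names(x)) {
    cat(sprintf("  %-13s %s\n", key,
                if (is.null(x[[key]])) "NULL" else format(x[[key]])))
  }
  cat(sprintf("  config hash %s (regbind %s)\n",
              substr(prov$config_hash, 1, 8), prov$package_version))
  invisible(x)
}
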