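#' Write / read arrangement layouts as long-format CSV
#'
#' Columns: `participant`, `session`, `trial_index`, `word`, `x`, `y`,
#' `canvas_w`, `canvas_h`.
#'
#' @param layouts named list: `layouts[[participant]][[session]]` is a list
#'   of trial layouts.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_arrangements_csv <- function(layouts, path) {
  rows <- list()
  for (pid in names(layouts)) {
    for (ses in names(layouts[[pid]])) {
      for (lay in layouts[[pid]][[ses]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          participant = pid, session = ses, trial_index = lay$trial_index,
          word = lay$positions$word_id, x = lay$positions$x, y = lay$positions$y,
          canvas_w = lay$canvas[1], canvas_h = lay$canvas[2],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_arrangements_csv
#' @return for the reader: the nested layout list.
#' @export
read_arrangements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("participant", "session", "trial_index", "word",
                       "x", "y", "canvas_w", "canvas_h"), basename(path))
  if (!is.numeric(df$x) || !is.numeric(df$y)) stop("non-numeric coordinates in ", path)
  out <- list()
  for (pid in unique(df$participant)) {
    dp <- df[df$participant == pid, ]
    out[[pid]] <- lapply(split(dp, dp$session), function(ds) {
      lapply(split(ds, ds$trial_index), function(dt) {
        if (anyDuplicated(dt$word)) stop("duplicate word within a trial in ", path)
        list(trial_index = dt$trial_index[1L],
             positions = data.frame(word_id = dt$word, x = dt$x, y = dt$y,
                                    stringsAsFactors = FALSE),
             canvas = c(dt$canvas_w[1L], dt$canvas_h[1L]))
      })
    })
  }
  out
}

#' Write / read the pair table as TSV
#'
#' @param pairs pair table.
#' @param path file path.
#' @return `path` (writer) / the pair table (reader).
#' @export
write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot_cols(df, c("pair_id", "cue_id", "target_id", "relatedness"),
                 basename(path))
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_id in ", path)
  df
}

#' Write / read a cued-recall log as CSV
#'
#' @param records recall log.
#' @param path file path.
#' @return `path` (writer) / the log (reader).
#' @export
write_recall_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_recall_csv
#' @export
read_recall_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(response = "character"))
  stopifnot_cols(df, c("participant", "pair_id", "day", "phase", "response"),
                 basename(path))
  df$response[is.na(df$response)] <- ""
  df
}

#' Write / read word embeddings in word2vec text format
#'
#' First line `<n_words> <dim>`, then one line per word:
#' `<word> <v1> <v2> ...`.
#'
#' @param embeddings numeric matrix with word-id rownames.
#' @param path file path.
#' @return `path` (writer) / the embedding matrix (reader).
#' @export
write_embeddings_txt <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(embeddings), ncol(embeddings)), con)
  for (i in seq_len(nrow(embeddings))) {
    writeLines(paste(c(rownames(embeddings)[i],
                       format(embeddings[i, ], digits = 17)), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_embeddings_txt
#' @export
read_embeddings_txt <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed embeddings header in ", path)
  body <- lines[-1L][nzchar(lines[-1L])]
  if (length(body) != hdr[1L]) {
    stop(sprintf("embeddings header promises %d words but file has %d",
                 hdr[1L], length(body)))
  }
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != hdr[2L] + 1L)) stop("malformed embedding row in ", path)
  emb <- t(vapply(parts, function(p) as.numeric(p[-1L]), numeric(hdr[2L])))
  rownames(emb) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(rownames(emb))) stop("duplicate word in embeddings file")
  emb
}

#' Write / read a word-labeled square similarity matrix as CSV
#'
#' @param m square matrix with identical row/column names.
#' @param path file path.
#' @param tol symmetry tolerance on read (default `1e-8`).
#' @return `path` (writer) / the matrix (reader).
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path, tol = 1e-8) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop("not a word-labeled square matrix: ", path)
  }
  if (max(abs(m - t(m)), na.rm = TRUE) > tol) {
    stop("matrix is asymmetric beyond tolerance: ", path)
  }
  (m + t(m)) / 2
}

#' Read a pipeline configuration from YAML
#'
#' Synthetic-mode fields are passed to [sim_config()]; analysis parameters
#' (`k_impute`, `k_neighbors`, `lure_edges`, `alpha`, `seed`) keep the
#' pipeline defaults unless overridden.
#'
#' @param path YAML file.
#' @return named list of configuration values.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(k_impute = 40L, k_neighbors = 20L,
                   lure_edges = c(0.2, 0.4, 0.6), alpha = 0.05, seed = 1L)
  utils::modifyList(defaults, cfg)
}

#' Write a JSON results summary with provenance
#'
#' @param results list of scalar summaries.
#' @param path output path.
#' @param config configuration list recorded alongside (hashed).
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(results, path, config = NULL) {
  payload <- list(results = results)
  if (!is.null(config)) {
    payload$provenance <- list(
      config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))),
      seed = config$seed,
      package_version = as.character(utils::packageVersion("swatrsa"))
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export all result tables of a pipeline run as tidy CSVs
#'
#' @param results a `swat_results` object.
#' @param dir output directory (created if needed).
#' @return character vector of files written.
#' @export
write_results_csv <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in c("pair_changes", "asymmetry", "lures", "accuracy", "summary")) {
    tab <- results[[nm]]
    if (is.null(tab)) next
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
  }
  files
}
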