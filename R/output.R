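#' Write flux coupling results to TSV and JSON
#'
#' Writes three files under `prefix`: `<prefix>_couplings.tsv` (columns
#' `reaction_a`, `reaction_b`, `relation` in `directional` / `partial`;
#' directional rows mean `reaction_a -> reaction_b`, partial pairs appear
#' once), `<prefix>_blocked.txt` (one blocked reaction per line) and
#' `<prefix>_fca.json` (a JSON mirror of both plus the class partition).
#'
#' @param table a [fca()] result.
#' @param prefix output path prefix.
#' @return invisibly, the written file paths.
#' @export
write_fca_results <- function(table, prefix) {
  stopifnot(inherits(table, "coupling_table"))
  pairs <- coupling_pairs(table, level = "reaction")
  names(pairs) <- c("reaction_a", "reaction_b", "relation")
  tsv <- paste0(prefix, "_couplings.tsv")
  utils::write.table(pairs, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  blocked_file <- paste0(prefix, "_blocked.txt")
  writeLines(table$blocked, blocked_file)
  json <- paste0(prefix, "_fca.json")
  jsonlite::write_json(
    list(unblocked = table$unblocked, blocked = table$blocked,
         classes = table$classes,
         couplings = pairs),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, blocked_file, json))
}

#' Write joint-coupling records as JSON lines and a TSV summary
#'
#' Each JSON line is
#' `{"pair": [r, s], "targets": [...], "unblocked_after": [...],
#' "has_joint_effect": bool}`.  The TSV summary has one row per record
#' with the pair, the number of target classes and of target reactions.
#'
#' @param dko a [double_knockout_analysis()] result.
#' @param jsonl_path,tsv_path output paths (either may be `NULL` to skip).
#' @return invisibly, the written file paths.
#' @export
write_joint_records <- function(dko, jsonl_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(dko, "dko_analysis"))
  written <- character()
  if (!is.null(jsonl_path)) {
    lines <- vapply(dko$records, function(rec) {
      as.character(jsonlite::toJSON(
        list(pair = I(rec$pair), targets = I(rec$targets),
             unblocked_after = I(rec$unblocked_after),
             has_joint_effect = jsonlite::unbox(rec$has_joint_effect)),
        digits = NA))
    }, character(1))
    writeLines(lines, jsonl_path)
    written <- c(written, jsonl_path)
  }
  if (!is.null(tsv_path)) {
    table <- dko$table
    df <- do.call(rbind, lapply(dko$records, function(rec) {
      data.frame(pair_a = rec$pair[1], pair_b = rec$pair[2],
                 n_target_classes = length(unique(table$class_map[rec$targets])),
                 n_target_reactions = length(rec$targets),
                 has_joint_effect = rec$has_joint_effect,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) {
      df <- data.frame(pair_a = character(), pair_b = character(),
                       n_target_classes = integer(),
                       n_target_reactions = integer(),
                       has_joint_effect = logical())
    }
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

#' Read joint-coupling records back from a JSON-lines file
#' @param jsonl_path path written by [write_joint_records()].
#' @return list of `joint_coupling_record` objects.
#' @export
read_joint_records <- function(jsonl_path) {
  lines <- readLines(jsonl_path)
  lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    structure(list(pair = as.character(x$pair),
                   targets = as.character(x$targets),
                   unblocked_after = as.character(x$unblocked_after),
                   has_joint_effect = isTRUE(x$has_joint_effect)),
              class = "joint_coupling_record")
  })
}

#' Write gene-knockout records as JSON lines and a TSV summary
#'
#' JSON lines of the form `{"genes": [...], "associated": [...],
#' "coupled": [...]}`; the TSV summary has columns `gene_set` (comma
#' separated), `n_associated`, `n_coupled`.
#'
#' @param records list of [gene_coupling()] records.
#' @param jsonl_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the written file paths.
#' @export
write_gene_records <- function(records, jsonl_path = NULL, tsv_path = NULL) {
  written <- character()
  if (!is.null(jsonl_path)) {
    lines <- vapply(records, function(rec) {
      as.character(jsonlite::toJSON(
        list(genes = I(rec$genes), associated = I(rec$associated),
             coupled = I(rec$coupled)), digits = NA))
    }, character(1))
    writeLines(lines, jsonl_path)
    written <- c(written, jsonl_path)
  }
  if (!is.null(tsv_path)) {
    df <- do.call(rbind, lapply(records, function(rec) {
      data.frame(gene_set = paste(rec$genes, collapse = ","),
                 n_associated = length(rec$associated),
                 n_coupled = length(rec$coupled),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(df)) {
      df <- data.frame(gene_set = character(), n_associated = integer(),
                       n_coupled = integer())
    }
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}

summary_to_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
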