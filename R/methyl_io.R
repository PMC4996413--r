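# Readers and writers for the pipeline's on-disk formats.
#
# All dialects are plain text: UTF-8, tab- or comma-separated, '.' decimal,
# no quoting of identifiers, so that write -> read round-trips are bit exact.
# Readers reject malformed input rather than silently coercing it.

#' Validate a sample sheet
#'
#' Checks the structural invariants of a sample sheet: required columns,
#' unique sample ids, QC rows labelled `QC`, and every pair id occurring on
#' exactly one control and one case row.
#'
#' @param sheet A data frame with columns `sample_id`, `class`, `chip`,
#'   `pair`, `cohort`, `split`.
#' @return The validated sheet (invisibly the same data frame).
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "class", "chip", "pair", "cohort", "split")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet lacks column(s): ", paste(missing, collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup))
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  qc_bad <- sheet$cohort == "QC" & sheet$class != "QC"
  if (any(qc_bad)) stop("QC-cohort rows must have class 'QC'")
  paired <- sheet[!is.na(sheet$pair), , drop = FALSE]
  for (p in unique(paired$pair)) {
    cls <- paired$class[paired$pair == p]
    if (length(cls) != 2L || sum(cls == "control") != 1L)
      stop(sprintf("pair '%s' must pair exactly one control with one case", p))
  }
  sheet
}

#' Write / read a two-channel intensity table
#'
#' The on-disk dialect is a TSV with probe ids in the first column and two
#' columns per sample, `<sample>.meth` and `<sample>.unmeth`.
#'
#' @param ds An `intensity_dataset`.
#' @param path Output file.
#' @return `write_intensity_table` returns `path` invisibly;
#'   `read_intensity_table` returns an `intensity_dataset` (without sheet —
#'   attach one with [read_sample_sheet()]).
#' @export
write_intensity_table <- function(ds, path) {
  cols <- as.vector(rbind(paste0(ds$samples, ".meth"),
                          paste0(ds$samples, ".unmeth")))
  mat <- matrix(0, nrow = length(ds$probes), ncol = length(cols),
                dimnames = list(ds$probes, cols))
  mat[, seq(1L, ncol(mat), by = 2L)] <- ds$meth
  mat[, seq(2L, ncol(mat), by = 2L)] <- ds$unmeth
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))   # %.17g: lossless double round trip
  df <- data.frame(probe = ds$probes, chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_intensity_table
#' @param sheet Optional sample sheet to attach and validate against.
#' @export
read_intensity_table <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (names(df)[1L] != "probe") stop("first column must be 'probe'")
  cols <- names(df)[-1L]
  meth_cols <- grep("\\.meth$", cols, value = TRUE)
  unmeth_cols <- grep("\\.unmeth$", cols, value = TRUE)
  samples_m <- sub("\\.meth$", "", meth_cols)
  samples_u <- sub("\\.unmeth$", "", unmeth_cols)
  odd <- c(setdiff(samples_m, samples_u), setdiff(samples_u, samples_m))
  if (length(odd))
    stop("mismatched channel columns for sample(s): ",
         paste(sort(unique(odd)), collapse = ", "))
  if (length(cols) != length(meth_cols) + length(unmeth_cols))
    stop("columns must all follow the '<sample>.meth'/'<sample>.unmeth' dialect")
  samples <- samples_m
  meth <- as.matrix(df[, paste0(samples, ".meth"), drop = FALSE])
  unmeth <- as.matrix(df[, paste0(samples, ".unmeth"), drop = FALSE])
  if (any(!is.finite(meth)) || any(!is.finite(unmeth)))
    stop("non-finite intensity value in ", path)
  if (any(meth < 0) || any(unmeth < 0))
    stop("negative intensity value in ", path)
  dimnames(meth) <- dimnames(unmeth) <- list(df$probe, samples)
  if (!is.null(sheet)) {
    sheet <- validate_sample_sheet(sheet)
    if (!setequal(sheet$sample_id, samples))
      stop("sample sheet and intensity table disagree on sample ids")
    sheet <- sheet[match(samples, sheet$sample_id), , drop = FALSE]
  }
  structure(list(probes = df$probe, samples = samples,
                 meth = meth, unmeth = unmeth, sheet = sheet),
            class = "intensity_dataset")
}

#' Write / read a sample sheet CSV
#'
#' @param sheet A sample sheet data frame.
#' @param path File path.
#' @return The path (write) or the validated sheet (read).
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet[, c("sample_id", "class", "chip", "pair",
                               "cohort", "split")],
                     path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sheet <- utils::read.table(path, header = TRUE, sep = ",",
                             stringsAsFactors = FALSE, na.strings = "",
                             comment.char = "")
  validate_sample_sheet(sheet)
}

#' Parse an OBO-format ontology subset
#'
#' Reads `[Term]` stanzas honouring `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` tags only. Obsolete terms are skipped; `part_of` and other
#' relationship types are ignored. The resulting graph must be acyclic.
#'
#' @param path OBO file.
#' @return A `go_graph`.
#' @export
parse_obo_subset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && nzchar(cur$id))
      terms[[cur$id]] <- cur
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = "", name = "", aspect = NA_character_,
                  parents = character(0), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { terms <- flush(cur, terms); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur$id <- trimws(sub("^id:", "", ln))
    else if (grepl("^name:", ln)) cur$name <- trimws(sub("^name:", "", ln))
    else if (grepl("^namespace:", ln)) cur$aspect <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln))
      cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", ln)))
    else if (grepl("^is_obsolete:\\s*true", ln)) cur$obsolete <- TRUE
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop("no terms parsed from ", path)
  ids <- vapply(terms, `[[`, character(1), "id")
  term_df <- data.frame(id = ids,
                        name = vapply(terms, `[[`, character(1), "name"),
                        aspect = vapply(terms, `[[`, character(1), "aspect"),
                        stringsAsFactors = FALSE, row.names = NULL)
  edges <- do.call(rbind, lapply(terms, function(t) {
    p <- intersect(t$parents, ids)   # edges to terms outside the subset dropped
    if (!length(p)) return(NULL)
    data.frame(child = t$id, parent = p, stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0))
  go_graph(term_df, edges)
}

#' Write a small ontology as an OBO subset
#'
#' @param graph A `go_graph`.
#' @param path Output file.
#' @export
write_obo_subset <- function(graph, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$id[i]
    writeLines(c("", "[Term]", paste0("id: ", id),
                 paste0("name: ", graph$terms$name[i]),
                 paste0("namespace: ", graph$terms$aspect[i])), con)
    for (p in graph$parents[[id]])
      writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}

#' Read / write a two-column gene annotation TSV
#'
#' Lines are `gene<TAB>term`. Duplicate associations are de-duplicated;
#' associations to terms absent from `graph` are dropped with a warning
#' reporting their count.
#'
#' @param path TSV file.
#' @param graph A `go_graph` used to screen term ids.
#' @return An `annotation_corpus`.
#' @export
parse_gene_annotation <- function(path, graph) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "",
                          col.names = c("gene", "term"))
  if (!nrow(df)) stop("empty annotation file: ", path)
  df <- unique(df)
  annotation_corpus(df, graph)
}

#' @rdname parse_gene_annotation
#' @param corpus An `annotation_corpus` to serialize (direct annotations).
#' @export
write_gene_annotation <- function(corpus, path) {
  df <- corpus$annotations[order(corpus$annotations$gene,
                                 corpus$annotations$term), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read a probe annotation table
#'
#' TSV with columns probe, semicolon-joined gene list, region group.
#'
#' @param probe_annotation Data frame probe/gene/region (one row per
#'   probe-gene link).
#' @param path File path.
#' @export
write_probe_annotation <- function(probe_annotation, path) {
  sp <- split(probe_annotation$gene, probe_annotation$probe)
  reg <- vapply(split(probe_annotation$region, probe_annotation$probe),
                function(r) r[1L], character(1))
  df <- data.frame(probe = names(sp),
                   genes = vapply(sp, function(g)
                     paste(sort(unique(g)), collapse = ";"), character(1)),
                   region = reg, stringsAsFactors = FALSE)
  df <- df[order(df$probe), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_probe_annotation
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "")
  long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    genes <- strsplit(df$genes[i], ";", fixed = TRUE)[[1L]]
    data.frame(probe = df$probe[i], gene = genes, region = df$region[i],
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Write a report deterministically as JSON
#'
#' Serializes a (possibly nested) report list to JSON with stable key order
#' and no rounding. `NaN` metrics are serialized as `null` with a warning.
#'
#' @param report A serializable list (include the config echo and seed
#'   yourself; [run_pipeline()] does).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  has_nan <- function(x) {
    if (is.list(x)) return(any(vapply(x, has_nan, logical(1))))
    is.numeric(x) && any(is.nan(x))
  }
  if (has_nan(report)) warning("NaN metric serialized as null")
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE,
                           force = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
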