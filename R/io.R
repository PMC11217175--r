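## Readers/writers for the three plain-text interchange formats: expression
## matrices (TSV/CSV, genes x samples), sample metadata tables, and GMT gene
## set collections. Delimiter is auto-detected from the header line; mixed
## tab+comma headers are rejected. Gene identifiers are opaque case-sensitive
## strings and parsing is locale-independent (decimal point only).

.detectSep <- function(path) {
    header <- readLines(path, n = 1L)
    if (!length(header)) stop(sprintf("'%s' is empty", path))
    tab <- grepl("\t", header, fixed = TRUE)
    com <- grepl(",", header, fixed = TRUE)
    if (tab && com)
        stop(sprintf("mixed delimiters (tab and comma) in header of '%s'", path))
    if (!tab && !com)
        stop(sprintf("could not detect a tab or comma delimiter in '%s'", path))
    if (tab) "\t" else ","
}

.readDelim <- function(path, sep) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    fields <- strsplit(lines, sep, fixed = TRUE)
    n <- lengths(fields)
    if (any(n != n[1L]))
        stop(sprintf("ragged table in '%s': line %d has %d field(s), expected %d",
                     path, which(n != n[1L])[1L], n[n != n[1L]][1L], n[1L]))
    do.call(rbind, fields)
}

#' Read a gene x sample expression matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose header row holds sample identifiers, auto-detecting tab versus comma
#' delimiters. File order of genes and samples is preserved.
#'
#' @param path path to the TSV/CSV file.
#' @param missingPolicy `"error"` (default) aborts on any missing cell;
#'   `"drop_gene"` removes every gene row containing a missing cell and
#'   reports the count. Non-numeric cells are always a parse error.
#'
#' @return numeric matrix with gene rownames and sample colnames.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, missingPolicy = c("error", "drop_gene")) {
    missingPolicy <- match.arg(missingPolicy)
    sep <- .detectSep(path)
    cells <- .readDelim(path, sep)
    if (nrow(cells) < 2L || ncol(cells) < 2L)
        stop(sprintf("'%s' must contain a header row and at least one gene and sample",
                     path))
    sampleIds <- cells[1L, -1L]
    geneIds <- cells[-1L, 1L]
    if (anyDuplicated(sampleIds))
        stop(sprintf("duplicated sample id(s) in '%s': %s", path,
                     paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", ")))
    if (anyDuplicated(geneIds))
        stop(sprintf("duplicated gene id(s) in '%s': %s", path,
                     paste(unique(geneIds[duplicated(geneIds)]), collapse = ", ")))
    raw <- cells[-1L, -1L, drop = FALSE]
    vals <- suppressWarnings(array(as.numeric(raw), dim(raw)))
    isMissing <- raw %in% c("", "NA", "na", "NaN")
    bad <- which(is.na(vals) & !isMissing, arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s' in '%s'",
                     raw[bad[1L, 1L], bad[1L, 2L]], geneIds[bad[1L, 1L]],
                     sampleIds[bad[1L, 2L]], path))
    vals[isMissing] <- NA_real_
    dimnames(vals) <- list(geneIds, sampleIds)
    if (anyNA(vals)) {
        if (missingPolicy == "error")
            stop(sprintf("missing value(s) in '%s' (first at gene '%s'); use missingPolicy = \"drop_gene\" to drop affected genes",
                         path, geneIds[which(rowSums(is.na(vals)) > 0)[1L]]))
        drop <- rowSums(is.na(vals)) > 0
        message(sprintf("dropping %d gene(s) with missing values", sum(drop)))
        vals <- vals[!drop, , drop = FALSE]
    }
    vals
}

#' Write an expression matrix to delimited text
#'
#' Numbers are written with 17 significant digits so that
#' `readExpression(writeExpression(x))` reproduces `x` exactly.
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, sep = "\t") {
    stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
    header <- paste(c("gene_id", colnames(x)), collapse = sep)
    body <- vapply(seq_len(nrow(x)), function(i)
        paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep), "")
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: set name, description, then tab-separated member genes
#' (Broad dialect). Duplicate members within a line are collapsed with a
#' warning; duplicate set names are an error.
#'
#' @param path path to the GMT file.
#' @return a [GeneSetCollection].
#' @seealso [writeGMT()]
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    keep <- nzchar(lines)
    lineNo <- which(keep)
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    short <- lengths(fields) < 3L
    if (any(short))
        stop(sprintf("GMT line %d of '%s' has fewer than 3 fields",
                     lineNo[short][1L], path))
    setNames_ <- vapply(fields, `[`, "", 1L)
    if (anyDuplicated(setNames_))
        stop(sprintf("duplicated gene set name(s) in '%s': %s", path,
                     paste(unique(setNames_[duplicated(setNames_)]), collapse = ", ")))
    desc <- vapply(fields, `[`, "", 2L)
    sets <- lapply(fields, function(f) f[-(1:2)])
    ndup <- vapply(sets, function(s) sum(duplicated(s)), 0L)
    if (any(ndup > 0L)) {
        warning(sprintf("collapsed duplicated members in set(s): %s",
                        paste(setNames_[ndup > 0L], collapse = ", ")))
        sets <- lapply(sets, unique)
    }
    names(sets) <- setNames_
    GeneSetCollection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a [GeneSetCollection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(gsc, path) {
    stopifnot(is(gsc, "GeneSetCollection"))
    lines <- vapply(seq_along(gsc), function(i)
        paste(c(names(gsc)[i], gsc@description[i], gsc@sets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text with required columns `sample_id`, `patient_id`,
#' `timepoint` (`pre`/`post`) and `group` (`PR`/`AR`); optional outcome
#' columns `progression_days`, `progression_event`, `survival_days`,
#' `survival_event`. Vocabulary and design invariants (one sample per
#' patient and timepoint, group constant within patient) are enforced.
#'
#' @param path path to the TSV/CSV file.
#' @return a data.frame, one row per sample.
#' @seealso [writeMetadata()], [ResistanceExperiment()]
#' @export
readMetadata <- function(path) {
    sep <- .detectSep(path)
    cells <- .readDelim(path, sep)
    header <- cells[1L, ]
    df <- as.data.frame(cells[-1L, , drop = FALSE], stringsAsFactors = FALSE)
    colnames(df) <- header
    for (col in c("progression_days", "survival_days"))
        if (col %in% header) df[[col]] <- as.numeric(df[[col]])
    for (col in c("progression_event", "survival_event"))
        if (col %in% header) df[[col]] <- as.logical(df[[col]])
    msg <- .checkMetadata(df)
    if (length(msg))
        stop(sprintf("invalid metadata in '%s': %s", path,
                     paste(msg, collapse = "; ")))
    df
}

#' Write a sample metadata table
#'
#' @param meta data.frame as returned by [readMetadata()].
#' @param path output path.
#' @param sep field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
writeMetadata <- function(meta, path, sep = "\t") {
    fmt <- function(v) {
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }
    cols <- lapply(meta, fmt)
    header <- paste(colnames(meta), collapse = sep)
    body <- do.call(paste, c(cols, sep = sep))
    writeLines(c(header, body), path)
    invisible(path)
}
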