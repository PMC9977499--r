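## On-disk formats: TSV expression matrix + two-column groups table, BED3/6
## intervals, GMT gene sets, TSV/JSON results. All readers validate hard and
## name the offending line/cell; all writers use a frozen float format
## (scientific, 6 significant digits) so outputs are byte-stable.

#' Read an expression matrix and its sample-group table
#'
#' The expression file is a TSV whose header row holds sample IDs and whose
#' first column holds feature IDs; the groups file is a two-column TSV with
#' header `sample_id<TAB>group`. Every sample in the matrix must appear in
#' the groups file and vice versa.
#'
#' @param path expression matrix TSV.
#' @param groupsPath two-column sample-to-group TSV.
#' @param scale scale marker of the stored values, `"log2"` or `"linear"`.
#' @return An [ExpressionTable-class].
#' @export
readExpression <- function(path, groupsPath, scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    for (p in c(path, groupsPath))
        if (!file.exists(p)) stop(sprintf("file not found: %s", p))
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             colClasses = "character", row.names = NULL)
    if (ncol(raw) < 2L)
        stop("expression file needs a feature-ID column plus >= 1 sample")
    fids <- raw[[1L]]
    sids <- colnames(raw)[-1L]
    if (anyDuplicated(fids))
        stop(sprintf("duplicate feature ID: '%s'",
                     fids[duplicated(fids)][1L]))
    if (anyDuplicated(sids))
        stop(sprintf("duplicate sample ID: '%s'",
                     sids[duplicated(sids)][1L]))
    vals <- suppressWarnings(
        vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
    vals <- matrix(vals, nrow = nrow(raw),
                   dimnames = list(fids, sids))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric value at feature '%s', sample '%s'",
                     fids[bad[1L, 1L]], sids[bad[1L, 2L]]))
    grp <- utils::read.delim(groupsPath, header = TRUE,
                             check.names = FALSE,
                             colClasses = "character")
    if (ncol(grp) < 2L)
        stop("groups file must have two columns: sample_id, group")
    ExpressionTable(vals, stats::setNames(grp[[2L]], grp[[1L]]),
                    scale = scale)
}

#' Write an expression matrix and groups table
#'
#' Inverse of [readExpression()]; values are written with the package's
#' frozen numeric format so write/read round-trips are exact at that
#' precision.
#'
#' @param x an [ExpressionTable-class].
#' @param path,groupsPath output TSV paths (`groupsPath` optional).
#' @return Invisibly, the paths written.
#' @export
writeExpression <- function(x, path, groupsPath = NULL) {
    v <- exprValues(x)
    lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
               vapply(seq_len(nrow(v)), function(i)
                   paste(c(rownames(v)[i], .fmtNum(v[i, ])),
                         collapse = "\t"), character(1L)))
    writeLines(lines, path)
    out <- path
    if (!is.null(groupsPath)) {
        g <- sampleGroups(x)
        writeLines(c("sample_id\tgroup",
                     paste(names(g), as.character(g), sep = "\t")),
                   groupsPath)
        out <- c(path, groupsPath)
    }
    invisible(out)
}

#' Read a BED3+ file into a GRanges
#'
#' BED coordinates (0-based, half-open) are converted to the 1-based closed
#' convention of [GenomicRanges::GRanges]; [writeBed()] converts back, so
#' coordinates survive a read/write cycle unchanged. Columns beyond the
#' sixth are ignored; missing names are auto-generated and missing strands
#' become `"*"` (BED `"."`).
#'
#' @param path BED file.
#' @param requireUniqueNames error on duplicate interval names (default
#'   TRUE: gene models and single-subunit peak files both require them).
#' @return A named [GenomicRanges::GRanges].
#' @export
readBed <- function(path, requireUniqueNames = TRUE) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    ln <- readLines(path)
    keep <- which(nzchar(trimws(ln)))
    if (!length(keep))
        return(GenomicRanges::GRanges())
    fields <- strsplit(ln[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("line %d: BED needs >= 3 tab-separated fields",
                     keep[which(nf < 3L)[1L]]))
    get <- function(i) vapply(fields, function(f)
        if (length(f) >= i) f[i] else NA_character_, character(1L))
    chrom <- get(1L)
    s <- get(2L); e <- get(3L)
    badint <- !grepl("^[0-9]+$", s) | !grepl("^[0-9]+$", e)
    if (any(badint))
        stop(sprintf("line %d: non-integer coordinate",
                     keep[which(badint)[1L]]))
    start0 <- as.numeric(s); end0 <- as.numeric(e)
    if (any(start0 >= end0))
        stop(sprintf("line %d: start must be < end",
                     keep[which(start0 >= end0)[1L]]))
    nm <- get(4L)
    auto <- is.na(nm) | nm == "."
    nm[auto] <- sprintf("interval_%d", which(auto))
    if (requireUniqueNames && anyDuplicated(nm))
        stop(sprintf("duplicate interval name: '%s'",
                     nm[duplicated(nm)][1L]))
    strand <- get(6L)
    strand[is.na(strand)] <- "."
    if (!all(strand %in% c("+", "-", ".")))
        stop(sprintf("line %d: strand must be one of +, -, .",
                     keep[which(!strand %in% c("+", "-", "."))[1L]]))
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = start0 + 1, end = end0),
        strand = sub(".", "*", strand, fixed = TRUE))
    names(gr) <- nm
    gr
}

#' @rdname readBed
#' @param gr a named GRanges.
#' @export
writeBed <- function(gr, path) {
    if (!length(gr)) {
        writeLines(character(), path)
        return(invisible(path))
    }
    nm <- names(gr)
    if (is.null(nm)) nm <- sprintf("interval_%d", seq_along(gr))
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                       as.character(GenomicRanges::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr), nm, st),
               path)
    invisible(path)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member gene IDs (>= 3 fields).
#' Member lists are deduplicated preserving first-seen order.
#'
#' @param path GMT file.
#' @return A [GeneSetCollection-class].
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    ln <- readLines(path)
    keep <- which(nzchar(trimws(ln)))
    fields <- strsplit(ln[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("line %d: GMT needs >= 3 tab-separated fields",
                     keep[which(nf < 3L)[1L]]))
    nm <- vapply(fields, `[`, character(1L), 1L)
    if (anyDuplicated(nm))
        stop(sprintf("duplicate set name: '%s'", nm[duplicated(nm)][1L]))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    names(sets) <- nm
    desc <- vapply(fields, `[`, character(1L), 2L)
    methods::new("GeneSetCollection", sets = sets, descriptions = desc)
}

#' @rdname readGmt
#' @param x a `GeneSetCollection`.
#' @export
writeGmt <- function(x, path) {
    writeLines(vapply(seq_along(x@sets), function(i)
        paste(c(names(x@sets)[i], x@descriptions[i], x@sets[[i]]),
              collapse = "\t"), character(1L)), path)
    invisible(path)
}

## frozen output float format: scientific, 6 significant digits
.fmtNum <- function(x) {
    out <- character(length(x))
    num <- is.na(x) | is.nan(x) | is.infinite(x)
    out[num] <- as.character(x[num])
    out[!num] <- formatC(x[!num], format = "e", digits = 5L)
    out
}

.fmtCell <- function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmtNum(col)
    else as.character(col)
}

.writeTsv <- function(df, path) {
    cells <- lapply(df, .fmtCell)
    lines <- c(paste(colnames(df), collapse = "\t"),
               if (nrow(df)) do.call(paste, c(cells, sep = "\t")))
    writeLines(lines, path)
    invisible(path)
}

.asDataFrame <- function(x) {
    df <- as.data.frame(x)
    if (!is.null(rownames(df)) &&
        !identical(rownames(df), as.character(seq_len(nrow(df))))) {
        df <- cbind(feature_id = rownames(df), df)
        rownames(df) <- NULL
    }
    df
}

#' Write pipeline result tables plus a JSON run summary
#'
#' Writes one TSV per result object (fixed column order, scientific
#' 6-significant-digit float format) and a `run_summary.json` recording
#' parameters, seed and per-table row counts. Identical inputs produce
#' byte-identical outputs; no timestamps are embedded.
#'
#' @param results a named list; recognized names are `de`
#'   ([DEResults-class]), `ora` ([EnrichmentResults-class]), `targets`
#'   ([TargetEnrichmentResults-class]). Other entries must be data.frames
#'   and are written under their own names.
#' @param outDir output directory, created if needed.
#' @param params list of run parameters for the summary.
#' @param seed integer seed to record (or NULL).
#' @return Invisibly, the named vector of file paths written.
#' @export
writeResults <- function(results, outDir, params = list(), seed = NULL) {
    ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                           showWarnings = FALSE)
    if (!ok || file.access(outDir, 2L) != 0L)
        stop(sprintf("cannot write to directory: %s", outDir))
    paths <- c()
    counts <- list()
    for (nm in names(results)) {
        obj <- results[[nm]]
        if (is.null(obj)) next
        df <- if (nm == "targets" && methods::is(obj, "DFrame")) {
            d <- .asDataFrame(obj[, setdiff(colnames(obj), "target_genes")])
            d$target_genes <- vapply(obj$target_genes, paste,
                                     character(1L), collapse = ",")
            d
        } else .asDataFrame(obj)
        f <- file.path(outDir, paste0(nm, "_results.tsv"))
        .writeTsv(df, f)
        paths[nm] <- f
        counts[[nm]] <- nrow(df)
    }
    summary <- list(package = "nfkbtargets",
                    version = as.character(utils::packageVersion("nfkbtargets")),
                    parameters = params,
                    seed = seed,
                    rows = counts)
    jf <- file.path(outDir, "run_summary.json")
    jsonlite::write_json(summary, jf, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    paths["summary"] <- jf
    invisible(paths)
}
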