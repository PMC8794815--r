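#' Read ungapped single-end alignments from SAM or BED6
#'
#' Consumes aligned reads for density assignment. Unmapped, secondary and
#' supplementary SAM records are dropped, as are multi-mappers (NH tag > 1
#' when present, otherwise any query name occurring more than once) and reads
#' outside the length filter. Counts of reads dropped per reason are reported
#' with \code{message()}.
#'
#' @param path a SAM file (\code{.sam}) or BED6 file (\code{.bed}: chrom,
#'   start, end, name, score, strand).
#' @param lengthFilter inclusive read-length window in nt; the ribosome
#'   footprint default is 20-45, RNA-seq fragments are conventionally 25-45.
#' @param strict if \code{TRUE}, a gapped (non-\code{<len>M}) CIGAR aborts;
#'   otherwise such records are skipped with a warning.
#' @return A read table: \code{qname}, \code{rname}, \code{strand},
#'   \code{pos} (1-based leftmost), \code{len}.
#' @export
readAlignments <- function(path, lengthFilter = c(20L, 45L), strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 6L) stop("BED input needs 6 columns")
    reads <- data.frame(qname = as.character(bed[[4]]),
                        rname = as.character(bed[[1]]),
                        strand = as.character(bed[[6]]),
                        pos = bed[[2]] + 1L,          # BED is 0-based half-open
                        len = bed[[3]] - bed[[2]],
                        stringsAsFactors = FALSE)
  } else {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(bam), add = TRUE)
    flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
      flag = flags,
      what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "cigar"),
      tag = "NH")
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    nTotal <- Rsamtools::countBam(bam)$records
    nDroppedFlag <- nTotal - length(res$qname)
    if (nDroppedFlag > 0)
      message(nDroppedFlag, " unmapped/secondary/supplementary record(s) dropped")

    gapped <- !grepl("^[0-9]+M$", res$cigar)
    if (any(gapped)) {
      if (strict) stop(sum(gapped), " gapped alignment(s); rerun without strict")
      warning(sum(gapped), " gapped alignment(s) skipped")
    }
    nh <- res$tag$NH
    multi <- if (!is.null(nh) && !all(is.na(nh))) {
      !is.na(nh) & nh > 1L
    } else rep(FALSE, length(res$qname))
    reads <- data.frame(qname = res$qname,
                        rname = as.character(res$rname),
                        strand = as.character(res$strand),
                        pos = res$pos,
                        len = res$qwidth,
                        stringsAsFactors = FALSE)[!gapped & !multi, , drop = FALSE]
    nMulti <- sum(multi)
    # SAM dialects without NH: treat duplicated query names as multi-mappers
    dup <- reads$qname %in% reads$qname[duplicated(reads$qname)]
    if (any(dup)) {
      reads <- reads[!dup, , drop = FALSE]
      nMulti <- nMulti + sum(dup)
    }
    if (nMulti > 0) message(nMulti, " multi-mapping record(s) dropped")
  }
  short <- reads$len < lengthFilter[1] | reads$len > lengthFilter[2]
  if (any(short))
    message(sum(short), " read(s) outside length filter [",
            lengthFilter[1], ", ", lengthFilter[2], "] dropped")
  rownames(reads) <- NULL
  reads[!short, , drop = FALSE]
}

#' Read gene annotation from GFF3 plus an operon membership table
#'
#' Imports CDS features (1-based inclusive coordinates, \code{locus_tag}
#' attribute naming the gene) and joins operon membership (TSV with columns
#' \code{gene_id}, \code{operon_id}, \code{rank}). Coupling categories are
#' filled with [categorizeGenes()].
#'
#' @param gffPath GFF3 file of CDS features.
#' @param operonPath operon membership TSV; \code{NULL} treats every gene as
#'   its own single-gene transcription unit.
#' @return A \code{GRanges} annotation usable throughout the package.
#' @export
readAnnotation <- function(gffPath, operonPath = NULL) {
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  gr$gene_id <- if (!is.null(gr$locus_tag)) gr$locus_tag else gr$ID
  if (anyNA(gr$gene_id)) stop("CDS features must carry locus_tag or ID")
  gr$utr5_len <- if (!is.null(gr$utr5_len)) as.integer(gr$utr5_len) else NA_integer_
  gr$minus1_base <- if (!is.null(gr$minus1_base)) as.character(gr$minus1_base)
    else NA_character_
  if (!is.null(operonPath)) {
    op <- read.table(operonPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    i <- match(gr$gene_id, op$gene_id)
    if (anyNA(i)) stop("operon table lacks ", sum(is.na(i)), " gene(s)")
    gr$operon_id <- op$operon_id[i]
    gr$operon_rank <- as.integer(op$rank[i])
  } else {
    gr$operon_id <- gr$gene_id
    gr$operon_rank <- 1L
  }
  gr$leaderless <- FALSE
  categorizeGenes(gr)
}

#' Write a density track as bedGraph (one file per strand)
#'
#' @param track a [DensityTrack-class].
#' @param prefix path prefix; \code{<prefix>.plus.bedgraph} and
#'   \code{<prefix>.minus.bedgraph} are written.
#' @return Invisibly, the written paths.
#' @export
writeBedGraph <- function(track, prefix) {
  stopifnot(is(track, "DensityTrack"))
  paths <- character()
  for (strandName in c("plus", "minus")) {
    s <- if (strandName == "plus") "+" else "-"
    path <- paste0(prefix, ".", strandName, ".bedgraph")
    con <- file(path, "w")
    for (repl in names(track@tracks)) {
      rle <- track@tracks[[repl]][[s]]
      ends <- cumsum(S4Vectors::runLength(rle))
      starts <- ends - S4Vectors::runLength(rle) + 1L
      val <- S4Vectors::runValue(rle)
      keep <- val != 0
      if (any(keep))
        writeLines(paste(repl, starts[keep] - 1L, ends[keep],
                         format(val[keep], trim = TRUE), sep = "\t"), con)
    }
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}
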