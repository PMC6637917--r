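#' Construct a genome sequence record
#'
#' A single chromosome with an explicit topology flag. The organisms this
#' pipeline targets (Streptomyces and relatives) carry linear chromosomes,
#' so topology defaults to `"linear"`.
#'
#' @param chrom_id chromosome identifier.
#' @param sequence uppercase A/C/G/T/N string.
#' @param topology `"linear"` or `"circular"`.
#' @return an object of class `genome_seq` with fields `chrom_id`, `length`,
#'   `topology` and `sequence`.
#' @export
genome_seq <- function(chrom_id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(chrom_id = as.character(chrom_id),
         length = nchar(sequence),
         topology = topology,
         sequence = sequence),
    class = "genome_seq"
  )
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %s bp, %s\n", x$chrom_id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA file.
#' @return a named list of [genome_seq()] records in file order.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("FASTA format error: no records in ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate headers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- lapply(seq_along(seqs), function(i) {
    genome_seq(ids[i], as.character(seqs[[i]]))
  })
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes a [genome_seq()] or list of them.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome_seq")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "chrom_id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene` and `CDS` features that carry a `locus_tag` attribute.
#' Coordinates stay 1-based inclusive as in GFF3; minus-strand features keep
#' start < end (coordinates are never swapped).
#'
#' @param path GFF3 file.
#' @return data frame with columns `locus_tag`, `chrom_id`, `start`, `end`,
#'   `strand`, `product`, sorted by `start`.
#' @export
read_gff3 <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 format error in ", path, ": ",
                             conditionMessage(e))
  )
  gr <- gr[as.character(gr$type) %in% c("gene", "CDS")]
  if (length(gr) == 0L) stop("GFF3 format error: no gene/CDS features in ", path)
  tags <- if ("locus_tag" %in% names(GenomicRanges::mcols(gr))) {
    as.character(gr$locus_tag)
  } else {
    rep(NA_character_, length(gr))
  }
  missing <- is.na(tags) | tags == ""
  if (any(missing)) {
    warning(sum(missing), " feature(s) without locus_tag skipped")
    gr <- gr[!missing]
    tags <- tags[!missing]
  }
  product <- if ("product" %in% names(GenomicRanges::mcols(gr))) {
    as.character(gr$product)
  } else {
    rep(NA_character_, length(gr))
  }
  genes <- data.frame(
    locus_tag = tags,
    chrom_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    product = product,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$locus_tag)) {
    stop("GFF3 format error: duplicate locus_tag: ",
         paste(unique(genes$locus_tag[duplicated(genes$locus_tag)]),
               collapse = ", "))
  }
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("GFF3 format error: gene features must be stranded (+/-)")
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#'
#' @param genes data frame as returned by [read_gff3()].
#' @param path output file.
#' @param source source column value.
#' @export
write_gff3 <- function(genes, path, source = "topoclust") {
  stopifnot(all(c("locus_tag", "chrom_id", "start", "end", "strand")
                %in% names(genes)))
  attrs <- sprintf("ID=%s;locus_tag=%s", genes$locus_tag, genes$locus_tag)
  has_prod <- !is.na(genes$product %||% rep(NA, nrow(genes)))
  if (any(has_prod)) {
    attrs[has_prod] <- paste0(attrs[has_prod], ";product=",
                              genes$product[has_prod])
  }
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$chrom_id, source, genes$start, genes$end,
                   genes$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a raw count matrix with its sample sheet
#'
#' The counts file is TSV with a `gene` column followed by one column per
#' sample; the sample sheet is a TSV sidecar with columns `sample`,
#' `condition`, `replicate`.
#'
#' @param counts_path counts TSV.
#' @param samples_path sample-sheet TSV.
#' @return object of class `count_matrix`: list with integer matrix `counts`
#'   (genes x samples) and data frame `samples`.
#' @export
read_counts <- function(counts_path, samples_path) {
  raw <- utils::read.delim(counts_path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  if (names(raw)[1] != "gene") {
    stop("counts format error: first column must be 'gene'")
  }
  if (anyDuplicated(raw$gene)) {
    stop("counts format error: duplicate gene row: ",
         paste(unique(raw$gene[duplicated(raw$gene)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("counts format error: missing value at gene '%s', sample '%s'",
                 raw$gene[bad[1]], colnames(m)[bad[2]]))
  }
  if (any(m < 0) || any(m != round(m))) {
    bad <- which(m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "counts format error: negative or non-integer count at gene '%s', sample '%s'",
      raw$gene[bad[1]], colnames(m)[bad[2]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- raw$gene
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               comment.char = "#")
  count_matrix(m, samples)
}

#' Construct a count matrix object
#'
#' @param counts non-negative integer matrix, genes x samples, with
#'   dimnames.
#' @param samples data frame with columns `sample`, `condition`, `replicate`
#'   covering every column of `counts`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  need <- c("sample", "condition", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(counts), samples$sample)
  if (length(missing)) {
    stop("sample metadata missing for: ", paste(missing, collapse = ", "))
  }
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$condition), collapse = ", ")))
  invisible(x)
}

#' Write a count matrix and its sample sheet
#'
#' @param cm `count_matrix`.
#' @param counts_path counts TSV path.
#' @param samples_path sample-sheet TSV path.
#' @export
write_counts <- function(cm, counts_path, samples_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' Read an operon (transcription-unit) membership table
#'
#' TSV with columns `tu_id`, `locus_tag`, `order`; `order` is the position
#' of the gene in transcription order (1 = first transcribed).
#'
#' @param path TSV file.
#' @return data frame with those columns.
#' @export
read_operons <- function(path) {
  op <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("tu_id", "locus_tag", "order")
  if (!all(need %in% names(op))) {
    stop("operon table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(op$locus_tag)) {
    stop("operon table format error: a gene may belong to one TU only")
  }
  op[order(op$tu_id, op$order), need]
}

#' Write an operon membership table
#' @param operons data frame with `tu_id`, `locus_tag`, `order`.
#' @param path output TSV.
#' @export
write_operons <- function(operons, path) {
  utils::write.table(operons[, c("tu_id", "locus_tag", "order")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Resolve transcription units from an annotation and operon table
#'
#' Genes absent from the operon table become singleton transcription units
#' (tu_id = locus_tag). The transcription start position of a unit is the
#' `start` of its first transcribed gene on the plus strand and the `end` of
#' its first transcribed gene on the minus strand.
#'
#' @param genes annotation data frame ([read_gff3()]).
#' @param operons optional operon membership table ([read_operons()]).
#' @return data frame, one row per member gene: `tu_id`, `locus_tag`,
#'   `order`, `strand`, `tss_position`.
#' @export
transcription_units <- function(genes, operons = NULL) {
  if (is.null(operons) || nrow(operons) == 0L) {
    operons <- data.frame(tu_id = character(), locus_tag = character(),
                          order = integer(), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(operons$locus_tag, genes$locus_tag)
  if (length(unknown)) {
    stop("operon table references genes absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  singles <- setdiff(genes$locus_tag, operons$locus_tag)
  all_mem <- rbind(
    operons[, c("tu_id", "locus_tag", "order")],
    data.frame(tu_id = singles, locus_tag = singles,
               order = rep(1L, length(singles)), stringsAsFactors = FALSE)
  )
  idx <- match(all_mem$locus_tag, genes$locus_tag)
  all_mem$strand <- genes$strand[idx]
  all_mem$start <- genes$start[idx]
  all_mem$end <- genes$end[idx]
  # per-TU consistency and TSS
  sp <- split(all_mem, all_mem$tu_id)
  tss <- vapply(sp, function(d) {
    if (length(unique(d$strand)) != 1L) {
      stop("transcription unit ", d$tu_id[1],
           " mixes strands; members must share a strand")
    }
    first <- d[d$order == min(d$order), ]
    if (first$strand[1] == "+") first$start[1] else first$end[1]
  }, numeric(1))
  all_mem$tss_position <- tss[all_mem$tu_id]
  all_mem <- all_mem[order(all_mem$tu_id, all_mem$order),
                     c("tu_id", "locus_tag", "order", "strand", "tss_position")]
  rownames(all_mem) <- NULL
  all_mem
}

#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `condition`, `gene`, `replicate`, `ct`
#' (one row per technical replicate well).
#'
#' @param path TSV file.
#' @return data frame with those columns.
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "condition", "gene", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) {
    stop("Ct table format error: Ct values must be positive numbers")
  }
  ct[, need]
}

#' Write a qPCR Ct table
#' @param ct data frame as in [read_ct_table()].
#' @param path output TSV.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.table(ct[, c("sample", "condition", "gene", "replicate", "ct")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
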