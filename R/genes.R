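#' Gene model container
#'
#' A minimal one-transcript-per-gene representation sufficient for variant
#' location and coding-consequence annotation: gene spans plus CDS segments
#' with transcript-order ranks. Coordinates are 1-based inclusive (GFF3
#' native).
#'
#' @param genes data.frame with columns `gene_id, chrom, strand, start, end`.
#' @param cds data.frame with columns `gene_id, chrom, strand, start, end,
#'   exon_rank` (rank in transcript orientation, 1 = 5'-most CDS segment).
#' @return object of class `gene_models`.
#' @export
gene_models <- function(genes, cds) {
  need_g <- c("gene_id", "chrom", "strand", "start", "end")
  need_c <- c(need_g, "exon_rank")
  stopifnot(all(need_g %in% names(genes)), all(need_c %in% names(cds)))
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene ids", call. = FALSE)
  if (!all(cds$gene_id %in% genes$gene_id)) {
    stop("CDS rows reference unknown genes", call. = FALSE)
  }
  for (g in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == g, ]
    seg <- seg[order(seg$start), ]
    if (any(seg$end < seg$start)) stop("CDS with end < start: ", g, call. = FALSE)
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop("overlapping CDS segments in gene ", g, call. = FALSE)
    }
    gg <- genes[genes$gene_id == g, ]
    if (min(seg$start) < gg$start || max(seg$end) > gg$end) {
      stop("CDS outside gene span in gene ", g, call. = FALSE)
    }
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$exon_rank), , drop = FALSE]
  rownames(genes) <- rownames(cds) <- NULL
  structure(list(genes = genes, cds = cds), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d CDS segments on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$cds), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Simulate toy gene models along the chromosomes
#'
#' Places non-overlapping genes at roughly regular spacing, each with 1-5
#' CDS segments whose summed length is a multiple of 3 (exon boundaries
#' fall mid-codon, so all three phases occur). Used by the synthetic-data
#' bundle; real analyses read gene models from GFF3 instead.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param genes_per_mb gene density.
#' @param codon_range range of coding length per gene, in codons.
#' @param intron_range intron length range (bp).
#' @return a [gene_models()] object.
#' @export
simulate_genes <- function(chrom_lengths, genes_per_mb = 15,
                           codon_range = c(60, 400),
                           intron_range = c(100, 1500)) {
  gl <- list(); cl <- list(); gid <- 0L
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    n <- round(len / 1e6 * genes_per_mb)
    if (n < 1) next
    slot <- len / n
    for (i in seq_len(n)) {
      gid <- gid + 1L
      id <- sprintf("gene%05d", gid)
      n_ex <- sample.int(5, 1)
      cds_len <- 3 * sample(seq(codon_range[1], codon_range[2]), 1)
      cuts <- sort(sample.int(cds_len - 1, n_ex - 1))
      ex_len <- diff(c(0, cuts, cds_len))
      introns <- if (n_ex > 1) {
        sample(seq(intron_range[1], intron_range[2]), n_ex - 1, replace = TRUE)
      } else integer(0)
      body <- sum(ex_len) + sum(introns)
      lo <- floor(slot * (i - 1)) + 2000
      hi <- floor(slot * i) - 2000 - body
      if (hi <= lo) next
      start <- lo + sample.int(hi - lo, 1)
      strand <- sample(c("+", "-"), 1)
      s <- start
      seg <- data.frame(start = integer(n_ex), end = integer(n_ex))
      for (k in seq_len(n_ex)) {
        seg$start[k] <- s
        seg$end[k] <- s + ex_len[k] - 1
        s <- seg$end[k] + 1 + if (k < n_ex) introns[k] else 0
      }
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      gl[[length(gl) + 1L]] <- data.frame(
        gene_id = id, chrom = ch, strand = strand,
        start = start, end = max(seg$end), stringsAsFactors = FALSE)
      cl[[length(cl) + 1L]] <- data.frame(
        gene_id = id, chrom = ch, strand = strand,
        start = seg$start, end = seg$end, exon_rank = rank,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(gl)) {
    return(gene_models(
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer()),
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 exon_rank = integer())))
  }
  gene_models(do.call(rbind, gl), do.call(rbind, cl))
}

# GFF3 phase of each CDS segment, in transcript order
cds_phases <- function(widths) {
  before <- c(0, cumsum(widths)[-length(widths)])
  (3 - before %% 3) %% 3
}

#' Write gene models to GFF3
#'
#' @param gm a [gene_models()] object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(gm$genes))) {
    g <- gm$genes[i, ]
    tid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tpoolscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tpoolscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, tid, g$gene_id), con)
    seg <- gm$cds[gm$cds$gene_id == g$gene_id, ]
    seg <- seg[order(seg$exon_rank), ]
    ph <- cds_phases(seg$end - seg$start + 1)
    for (k in seq_len(nrow(seg))) {
      writeLines(sprintf("%s\tpoolscan\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
                         seg$chrom[k], seg$start[k], seg$end[k], seg$strand[k],
                         ph[k], tid, tid), con)
    }
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `CDS` features via \pkg{rtracklayer} and resolves the
#' CDS Parent chain (CDS -> mRNA -> gene). Only the first transcript per
#' gene is kept (one-transcript model).
#'
#' @param path a GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ty <- as.character(gr$type)
  gix <- ty == "gene"
  genes <- data.frame(
    gene_id = as.character(gr$ID[gix]),
    chrom = as.character(GenomicRanges::seqnames(gr)[gix]),
    strand = as.character(GenomicRanges::strand(gr)[gix]),
    start = GenomicRanges::start(gr)[gix],
    end = GenomicRanges::end(gr)[gix], stringsAsFactors = FALSE)
  # transcript -> gene map
  tix <- ty %in% c("mRNA", "transcript")
  t2g <- stats::setNames(
    vapply(gr$Parent[tix], function(p) as.character(p)[1], ""),
    as.character(gr$ID[tix]))
  cix <- ty == "CDS"
  parent <- vapply(gr$Parent[cix], function(p) as.character(p)[1], "")
  gene_of <- ifelse(parent %in% names(t2g), t2g[parent], parent)
  cds <- data.frame(
    gene_id = unname(gene_of),
    chrom = as.character(GenomicRanges::seqnames(gr)[cix]),
    strand = as.character(GenomicRanges::strand(gr)[cix]),
    start = GenomicRanges::start(gr)[cix],
    end = GenomicRanges::end(gr)[cix], stringsAsFactors = FALSE)
  cds <- cds[cds$gene_id %in% genes$gene_id, , drop = FALSE]
  # transcript-order rank
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  cds$exon_rank <- stats::ave(seq_len(nrow(cds)), cds$gene_id,
                              FUN = function(ix) {
                                r <- seq_along(ix)
                                if (cds$strand[ix[1]] == "-") r <- rev(r)
                                r
                              })
  gene_models(genes, cds)
}

#' Simulate a genome sequence consistent with markers and gene models
#'
#' Random nucleotide background; CDS regions are overwritten with open
#' reading frames (sense codons plus a final stop, reverse-complemented on
#' minus strand) and marker reference alleles are then planted at their
#' positions, so annotation and reference checks operate on a consistent
#' sequence.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param markers optional marker data.frame (`chrom, pos, ref`).
#' @param genes optional [gene_models()].
#' @return a [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_genome <- function(chrom_lengths, markers = NULL, genes = NULL) {
  seqs <- lapply(chrom_lengths, function(len) {
    Biostrings::DNAString(paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = ""))
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- names(chrom_lengths)
  if (!is.null(genes) && nrow(genes$genes) > 0) {
    stops <- c("TAA", "TAG", "TGA")
    sense <- setdiff(mkAllStrings(c("A", "C", "G", "T"), 3), stops)
    for (ch in names(genome)) {
      gg <- genes$genes[genes$genes$chrom == ch, ]
      if (!nrow(gg)) next
      at <- IRanges::IRanges(); val <- character()
      for (g in gg$gene_id) {
        seg <- genes$cds[genes$cds$gene_id == g, ]
        seg <- seg[order(seg$exon_rank), ]
        L <- sum(seg$end - seg$start + 1)
        ncod <- L %/% 3
        cod <- c(sample(sense, max(ncod - 1, 0), replace = TRUE),
                 sample(stops, 1))
        tx <- substr(paste(cod, collapse = ""), 1, L)
        if (seg$strand[1] == "-") {
          tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
        }
        seg <- seg[order(seg$start), ]
        off <- cumsum(c(0, seg$end - seg$start + 1))
        for (k in seq_len(nrow(seg))) {
          at <- c(at, IRanges::IRanges(seg$start[k], seg$end[k]))
          val <- c(val, substr(tx, off[k] + 1, off[k + 1]))
        }
      }
      genome[[ch]] <- Biostrings::replaceAt(genome[[ch]], at,
                                            Biostrings::DNAStringSet(val))
    }
  }
  if (!is.null(markers)) {
    for (ch in names(genome)) {
      mm <- markers[markers$chrom == ch, ]
      if (!nrow(mm)) next
      mm <- mm[order(mm$pos), ]
      at <- IRanges::IRanges(mm$pos, mm$pos + nchar(mm$ref) - 1)
      genome[[ch]] <- Biostrings::replaceAt(genome[[ch]], at,
                                            Biostrings::DNAStringSet(mm$ref))
    }
  }
  genome
}

# all k-mers over an alphabet (small k only)
mkAllStrings <- function(alphabet, k) {
  out <- alphabet
  for (i in seq_len(k - 1)) out <- as.vector(outer(out, alphabet, paste0))
  out
}
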