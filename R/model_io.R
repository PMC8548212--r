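#' Read a locus gene model from GFF3 or BED plus a genome FASTA
#'
#' Exon features are taken from a GFF3 file (type `exon`, labels from the `ID`
#' attribute) or a 6-column BED file (labels from the name column; BED input
#' is converted from its 0-based half-open convention). Exon roles and
#' annotated ATG/stop positions are supplied in a config block.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED (`.bed`) file.
#' @param genome_fasta FASTA file with the chromosome sequence(s).
#' @param config Optional list (or path to a JSON/YAML file containing one)
#'   with elements `roles`, `annotated_start`, `annotated_stop`, each a named
#'   list keyed by exon id. Positions are 1-based within the exon.
#' @return A [gene_model()].
#' @export
read_gene_model <- function(path, genome_fasta, config = NULL) {
  config <- read_model_config(config)
  lower <- tolower(path)
  if (grepl("\\.bed$", lower)) {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(bed) < 6) stop("BED input must have 6 columns (need name and strand)")
    feats <- data.frame(chrom = bed[[1]], start = bed[[2]] + 1, end = bed[[3]],
                        id = bed[[4]], strand = bed[[6]],
                        stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[as.character(gr$type) == "exon"]
    if (length(gr) == 0) stop("no exon features in ", path)
    feats <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        id = as.character(gr$ID),
                        strand = as.character(GenomicRanges::strand(gr)),
                        stringsAsFactors = FALSE)
  }
  strand <- unique(feats$strand)
  if (length(strand) != 1L || !strand %in% c("+", "-"))
    stop("exons must share one explicit strand")
  feats <- feats[order(feats$start, decreasing = (strand == "-")), ]
  exons <- lapply(seq_len(nrow(feats)), function(i) {
    id <- feats$id[i]
    exon(id,
         genomic_interval(feats$chrom[i], feats$start[i], feats$end[i], strand),
         role = (config$roles[[id]] %||% "internal"),
         annotated_start = config$annotated_start[[id]] %||% NA_real_,
         annotated_stop = config$annotated_stop[[id]] %||% NA_real_)
  })
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gene_model_from_sequence(exons, genome)
}

read_model_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", tolower(config))) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML config requires the yaml package")
      config <- yaml::read_yaml(config)
    } else {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("reading JSON config requires the jsonlite package")
      config <- jsonlite::fromJSON(config, simplifyVector = FALSE)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Write a gene model as GFF3
#'
#' @param model A [gene_model()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gene_model_gff3 <- function(model, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(
      start = vapply(model$exons, function(e) e$interval$start, numeric(1)),
      end = vapply(model$exons, function(e) e$interval$end, numeric(1))),
    strand = model$strand)
  gr$type <- "exon"
  gr$ID <- exon_ids(model)
  gr$source <- "fusionsplice"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
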