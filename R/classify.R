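#' Long-read QC filter configuration
#'
#' Defaults mirror common long-read RACE/PacBio practice for this locus:
#' remove the first 50 bases (primer and non-uniform composition), keep reads
#' with mean Phred quality of at least 10, and call a read "full-length" only
#' when it is at least 2 kb.
#'
#' @param min_mean_quality Minimum mean Phred quality (default 10).
#' @param head_trim Bases removed from the 5' end (default 50).
#' @param min_length_full Minimum read length for the full-length call
#'   (default 2000).
#' @param keep_unqualified Keep (and flag) reads that carry no quality string,
#'   e.g. CCS FASTA input (default `TRUE`).
#' @return List of class `read_filter_config`.
#' @export
read_filter_config <- function(min_mean_quality = 10, head_trim = 50,
                               min_length_full = 2000,
                               keep_unqualified = TRUE) {
  stopifnot(min_mean_quality >= 0, head_trim >= 0, min_length_full >= 0)
  structure(list(min_mean_quality = min_mean_quality, head_trim = head_trim,
                 min_length_full = min_length_full,
                 keep_unqualified = keep_unqualified),
            class = "read_filter_config")
}

#' Read long reads from FASTQ or FASTA
#'
#' @param path FASTQ (with qualities) or FASTA (qualities `NA`).
#' @return Data frame with columns `id`, `seq`, `qual` (Phred+33 string or
#'   `NA`).
#' @export
read_long_reads <- function(path) {
  fastq <- grepl("\\.f(ast)?q(\\.gz)?$", tolower(path))
  if (fastq) {
    # Biostrings warns about dropped mcols when qualities ride along; harmless
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    data.frame(id = sub("\\s.*$", "", names(x)),
               seq = as.character(x),
               qual = as.character(Biostrings::quality(x)),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    data.frame(id = sub("\\s.*$", "", names(x)), seq = as.character(x),
               qual = NA_character_, stringsAsFactors = FALSE, row.names = NULL)
  }
}

mean_phred <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || !nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Quality-filter and head-trim long reads
#'
#' Removes `head_trim` bases from the 5' end of every read, then keeps reads
#' whose mean Phred quality is at least `min_mean_quality`. Reads without a
#' quality string pass the quality gate by declared policy
#' (`keep_unqualified`) and are flagged in the `no_quality` column.
#'
#' @param reads Data frame as from [read_long_reads()].
#' @param config A [read_filter_config()].
#' @return Filtered data frame with an added `no_quality` flag column.
#' @export
qc_filter <- function(reads, config = read_filter_config()) {
  if (nrow(reads) == 0) {
    reads$no_quality <- logical(0)
    return(reads)
  }
  trim <- config$head_trim
  reads$seq <- substring(reads$seq, trim + 1)
  reads$qual <- ifelse(is.na(reads$qual), NA_character_,
                       substring(reads$qual, trim + 1))
  reads <- reads[nchar(reads$seq) > 0, , drop = FALSE]
  mq <- mean_phred(reads$qual)
  reads$no_quality <- is.na(mq)
  keep <- ifelse(reads$no_quality, config$keep_unqualified,
                 mq >= config$min_mean_quality)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Alignment record against an isoform template
#'
#' @param read_id,template_id Identifiers.
#' @param mapq Mapping quality.
#' @param blocks Two-column matrix of aligned blocks in template coordinates,
#'   0-based half-open, sorted and non-overlapping.
#' @return List of class `alignment_record`.
#' @export
alignment_record <- function(read_id, template_id, mapq, blocks) {
  blocks <- matrix(as.numeric(blocks), ncol = 2,
                   dimnames = list(NULL, c("start0", "end0")))
  if (nrow(blocks)) {
    o <- order(blocks[, 1])
    blocks <- blocks[o, , drop = FALSE]
    if (any(blocks[, 2] <= blocks[, 1]) ||
        (nrow(blocks) > 1 && any(blocks[-1, 1] < blocks[-nrow(blocks), 2])))
      stop("alignment blocks must be non-empty, sorted and non-overlapping")
  }
  structure(list(read_id = unname(as.character(read_id)),
                 template_id = unname(as.character(template_id)),
                 mapq = unname(as.numeric(mapq)), blocks = blocks),
            class = "alignment_record")
}

#' Exact junction-window matcher (aligner-free, error-free reads)
#'
#' Locates each read as an exact substring of each template and emits one
#' alignment record per read: against its unique matching template with MAPQ
#' 60, or against the first of several equally matching templates with MAPQ 0
#' (a multi-mapper, removed downstream by the MAPQ gate). Reads matching no
#' template get no record. Intended for desk-scale tests on error-free
#' simulated reads; real data goes through a spliced/long-read aligner and
#' [read_alignments_sam()] / [read_alignments_paf()].
#'
#' @param reads Data frame with `id`, `seq`.
#' @param templates List of [isoform_template()] objects.
#' @return List of [alignment_record()]s.
#' @export
align_exact <- function(reads, templates) {
  tseqs <- vapply(templates, function(t) t$seq, character(1))
  tids <- vapply(templates, function(t) t$id, character(1))
  out <- list()
  for (i in seq_len(nrow(reads))) {
    pos <- vapply(tseqs, function(ts)
      regexpr(reads$seq[i], ts, fixed = TRUE)[1], numeric(1))
    hit <- which(pos > 0)
    if (!length(hit)) next
    j <- hit[1]
    s0 <- pos[j] - 1
    out[[length(out) + 1L]] <- alignment_record(
      reads$id[i], tids[j], mapq = if (length(hit) == 1L) 60 else 0,
      blocks = cbind(s0, s0 + nchar(reads$seq[i])))
  }
  out
}

#' Read alignments from SAM (via Rsamtools) against a template FASTA
#'
#' @param sam_path SAM file of reads aligned to the template set.
#' @return List of [alignment_record()]s, one per primary aligned record;
#'   aligned blocks are the M/=/X/D runs of the CIGAR on the reference.
#' @export
read_alignments_sam <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag, what = c("qname", "mapq")))
  blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = GenomicAlignments::start(ga),
    ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  lapply(seq_along(ga), function(i) {
    b <- blocks[[i]]
    alignment_record(S4Vectors::mcols(ga)$qname[i],
                     as.character(GenomicAlignments::seqnames(ga))[i],
                     mapq = S4Vectors::mcols(ga)$mapq[i],
                     blocks = cbind(GenomicAlignments::start(b) - 1,
                                    GenomicAlignments::end(b)))
  })
}

#' Read alignments from PAF (minimap2 default output)
#'
#' PAF carries one target span per line (no per-block breakdown), which is
#' adequate for substitution-only alignments.
#'
#' @param paf_path PAF file.
#' @return List of [alignment_record()]s.
#' @export
read_alignments_paf <- function(paf_path) {
  paf <- utils::read.table(paf_path, sep = "\t", stringsAsFactors = FALSE,
                           fill = TRUE, comment.char = "")[, 1:12]
  names(paf) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                  "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  lapply(seq_len(nrow(paf)), function(i)
    alignment_record(paf$qname[i], paf$tname[i], paf$mapq[i],
                     cbind(paf$tstart[i], paf$tend[i])))
}

junction_spanned <- function(blocks, breakpoints, min_overhang) {
  vapply(breakpoints, function(bp) {
    any(blocks[, 1] <= bp - min_overhang & blocks[, 2] >= bp + min_overhang)
  }, logical(1))
}

#' Classify one alignment against its isoform template
#'
#' A junction is spanned iff one aligned block covers the window
#' `[breakpoint - min_overhang, breakpoint + min_overhang)` in template
#' coordinates. The read is assigned to the template iff its mapping quality
#' passes `min_mapq` and at least one junction is spanned.
#'
#' @param aln An [alignment_record()].
#' @param template The [isoform_template()] it is aligned to.
#' @param min_mapq MAPQ threshold (default 20).
#' @param min_overhang Minimum matched bases on each side of a breakpoint
#'   (default 8).
#' @return One-row data frame: `read_id`, `assigned` (template id or `NA`),
#'   `spanned_junctions` (comma-joined `donor-acceptor` labels),
#'   `covers_all_junctions`, `reason` (`pass`, `low_mapq`, `no_junction`).
#' @export
classify_alignment <- function(aln, template, min_mapq = 20, min_overhang = 8) {
  if (!identical(aln$template_id, template$id))
    stop("alignment is against template ", aln$template_id, ", not ", template$id)
  sp <- junction_spanned(aln$blocks, template$junctions$breakpoint, min_overhang)
  labels <- paste(template$junctions$donor, template$junctions$acceptor, sep = "-")
  if (is.na(aln$mapq) || aln$mapq < min_mapq) {
    reason <- "low_mapq"; assigned <- NA_character_
  } else if (!any(sp)) {
    reason <- "no_junction"; assigned <- NA_character_
  } else {
    reason <- "pass"; assigned <- template$id
  }
  data.frame(read_id = aln$read_id, assigned = assigned,
             spanned_junctions = paste(labels[sp], collapse = ","),
             covers_all_junctions = length(sp) > 0 && all(sp),
             reason = reason, stringsAsFactors = FALSE)
}

# templates compatible with a set of spanned junction labels
compatible_templates <- function(spanned_labels, templates) {
  Filter(function(t) {
    tl <- paste(t$junctions$donor, t$junctions$acceptor, sep = "-")
    all(spanned_labels %in% tl)
  }, templates)
}

#' Classify a set of reads from their template alignments
#'
#' Per read, the best (highest-MAPQ) alignment record is classified with
#' [classify_alignment()]; a read whose spanned-junction set is compatible
#' with more than one template is re-assigned to the set's most specific
#' member (the unique compatible template whose exon chain is contained in
#' every other compatible chain) or, failing uniqueness, marked `ambiguous`.
#' Every input read appears in exactly one output row.
#'
#' @param reads Data frame with `id`, `seq` (post-[qc_filter()]).
#' @param alignments List of [alignment_record()]s.
#' @param templates Named list of [isoform_template()]s.
#' @param min_mapq,min_overhang See [classify_alignment()].
#' @return Data frame of read assignments with columns `read_id`, `assigned`,
#'   `spanned_junctions`, `covers_all_junctions`, `read_length`, `reason`
#'   (`pass`, `low_mapq`, `no_junction`, `ambiguous`, `unaligned`).
#' @export
classify_reads <- function(reads, alignments, templates,
                           min_mapq = 20, min_overhang = 8) {
  tids <- vapply(templates, function(t) t$id, character(1))
  by_read <- split(alignments,
                   vapply(alignments, function(a) a$read_id, character(1)))
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    rid <- reads$id[i]
    alns <- by_read[[rid]]
    if (is.null(alns)) {
      return(data.frame(read_id = rid, assigned = NA_character_,
                        spanned_junctions = "", covers_all_junctions = FALSE,
                        read_length = nchar(reads$seq[i]),
                        reason = "unaligned", stringsAsFactors = FALSE))
    }
    best <- alns[[which.max(vapply(alns, function(a) a$mapq, numeric(1)))]]
    ti <- match(best$template_id, tids)
    if (is.na(ti)) stop("alignment references unknown template: ", best$template_id)
    row <- classify_alignment(best, templates[[ti]], min_mapq, min_overhang)
    row$read_length <- nchar(reads$seq[i])
    if (row$reason == "pass") {
      spanned <- strsplit(row$spanned_junctions, ",", fixed = TRUE)[[1]]
      comp <- compatible_templates(spanned, templates)
      if (length(comp) > 1L) {
        chains <- lapply(comp, function(t) t$exon_chain)
        minimal <- vapply(seq_along(comp), function(k)
          all(vapply(chains, function(ch) all(chains[[k]] %in% ch), logical(1))),
          logical(1))
        if (sum(minimal) == 1L) {
          row$assigned <- comp[[which(minimal)]]$id
        } else {
          row$assigned <- NA_character_
          row$reason <- "ambiguous"
          row$covers_all_junctions <- FALSE
        }
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize per-isoform read support
#'
#' A read is full-length for its assigned isoform when it is at least
#' `min_length_full` nt long and its aligned blocks span every junction of
#' the template. Full-length proportions are computed over all full-length
#' assigned reads and sum to 1 whenever any exist.
#'
#' @param assignments Data frame from [classify_reads()].
#' @param templates Named list of templates.
#' @param config A [read_filter_config()] (supplies `min_length_full`).
#' @return Data frame with one row per isoform: `isoform`,
#'   `junction_reads`, `full_length_reads`, `full_length_proportion` (`NaN`,
#'   flagged, when no full-length reads exist).
#' @export
summarize_support <- function(assignments, templates,
                              config = read_filter_config()) {
  tids <- vapply(templates, function(t) t$id, character(1))
  bad <- setdiff(stats::na.omit(assignments$assigned), tids)
  if (length(bad)) stop("assignments reference unknown templates: ",
                        paste(bad, collapse = ", "))
  assigned <- assignments[!is.na(assignments$assigned), , drop = FALSE]
  fl <- assigned[assigned$read_length >= config$min_length_full &
                   assigned$covers_all_junctions, , drop = FALSE]
  n_fl <- nrow(fl)
  data.frame(
    isoform = tids,
    junction_reads = as.integer(table(factor(assigned$assigned, levels = tids))),
    full_length_reads = as.integer(table(factor(fl$assigned, levels = tids))),
    full_length_proportion =
      as.integer(table(factor(fl$assigned, levels = tids))) /
        (if (n_fl > 0) n_fl else NaN),
    stringsAsFactors = FALSE, row.names = NULL)
}
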