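#' Variant tables
#'
#' Variants are plain data frames with columns `chrom`, `pos` (1-based),
#' `ref`, `alt` (single bases) and `sample`. [read_variants()] builds one
#' from a MAF-like TSV or a VCF; [tally_sbs96()] consumes it.
#'
#' @param path input file.
#' @param format `"maf"` for a TSV with columns chrom, pos, ref, alt,
#'   sample (extra columns ignored); `"vcf"` for a VCF. For multi-sample
#'   VCFs with genotypes, a variant is assigned to every sample whose
#'   genotype carries the ALT allele; without genotype columns all records
#'   go to a single pseudo-sample named after the file.
#' @return data.frame of variant records; non-SNV records are dropped and
#'   counted in attribute `"skipped"` (named integer vector of reasons).
#' @export
read_variants <- function(path, format = c("maf", "vcf")) {
  format <- match.arg(format)
  if (format == "maf") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "sample")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("variant TSV lacks columns: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    v <- df[need]
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package", call. = FALSE)
    }
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    base <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                       ref = fix$REF, alt = fix$ALT,
                       stringsAsFactors = FALSE)
    gt <- tryCatch(vcfR::extract.gt(vcf), error = function(e) NULL)
    if (is.null(gt) || ncol(gt) == 0L) {
      base$sample <- tools::file_path_sans_ext(basename(path))
      v <- base
    } else {
      recs <- lapply(colnames(gt), function(s) {
        carries <- !is.na(gt[, s]) & grepl("1", gt[, s], fixed = TRUE)
        if (!any(carries)) return(NULL)
        cbind(base[carries, , drop = FALSE],
              sample = s, stringsAsFactors = FALSE)
      })
      v <- do.call(rbind, recs)
      if (is.null(v)) v <- cbind(base[0, ], sample = character(0))
    }
  }
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(as.character(v$ref))
  v$alt <- toupper(as.character(v$alt))
  snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L &
    v$ref %in% c("A", "C", "G", "T") & v$alt %in% c("A", "C", "G", "T") &
    v$ref != v$alt
  out <- v[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(non_snv = sum(!snv))
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Tally SBS96 spectra from SNVs against a reference genome
#'
#' Each SNV is classified by its reference trinucleotide context. When the
#' reference base is a purine (A/G) the trinucleotide and the substitution
#' are reverse-complemented first, so every mutation is reported on the
#' pyrimidine-centred strand (the SBS96 convention). Soft-masked
#' (lowercase) reference bases are uppercased before classification.
#'
#' Records that cannot be classified are dropped, not fatal: a reference
#' base disagreeing with the FASTA, a flanking base outside A/C/G/T, a
#' position at a sequence edge, or a chromosome absent from the reference.
#' Dropped counts per reason are returned in attribute `"skipped"`.
#'
#' @param variants data.frame as from [read_variants()] (columns chrom,
#'   pos, ref, alt, sample).
#' @param reference a `Biostrings::DNAStringSet`, a named character vector
#'   of sequences, or a FASTA file path.
#' @param sample_ids optional sample universe; samples with zero accepted
#'   variants still appear as all-zero rows.
#' @return A [spectrum_matrix()] on the SBS96 schema with integer counts.
#' @export
tally_sbs96 <- function(variants, reference, sample_ids = NULL) {
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  seqs <- if (inherits(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    reference
  }
  seqs <- toupper(seqs)
  schema <- sbs96_schema()
  samples <- unique(c(sample_ids, as.character(variants$sample)))
  counts <- matrix(0L, length(samples), 96,
                   dimnames = list(samples, schema$channels))
  skipped <- c(missing_chrom = 0L, edge_position = 0L,
               ref_mismatch = 0L, bad_context = 0L)
  n <- nrow(variants)
  if (n > 0L) {
    for (i in seq_len(n)) {
      chrom <- as.character(variants$chrom[i])
      pos <- variants$pos[i]
      ref <- variants$ref[i]
      alt <- variants$alt[i]
      if (!chrom %in% names(seqs)) {
        skipped["missing_chrom"] <- skipped["missing_chrom"] + 1L
        next
      }
      seq <- seqs[[chrom]]
      if (is.na(seq)) {
        skipped["missing_chrom"] <- skipped["missing_chrom"] + 1L
        next
      }
      if (pos < 2L || pos > nchar(seq) - 1L) {
        skipped["edge_position"] <- skipped["edge_position"] + 1L
        next
      }
      tri <- substr(seq, pos - 1L, pos + 1L)
      if (substr(tri, 2, 2) != ref) {
        skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1L
        next
      }
      if (grepl("[^ACGT]", tri)) {
        skipped["bad_context"] <- skipped["bad_context"] + 1L
        next
      }
      if (ref %in% c("A", "G")) {  # collapse to pyrimidine-centred strand
        tri <- revcomp(tri)
        ref <- unname(COMPLEMENT[ref])
        alt <- unname(COMPLEMENT[alt])
      }
      chan <- paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]",
                     substr(tri, 3, 3))
      s <- as.character(variants$sample[i])
      counts[s, chan] <- counts[s, chan] + 1L
    }
  }
  out <- spectrum_matrix(counts, schema)
  attr(out, "skipped") <- skipped
  out
}
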