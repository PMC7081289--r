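#' Shannon entropy of a nucleotide sequence
#'
#' Base-2 entropy of the observed base composition, used to drop
#' low-complexity (homopolymer-like) contigs. `N` bases are excluded from
#' the frequency counts; a homopolymer scores 0 and a uniform 4-base
#' composition scores 2 bits.
#'
#' @param sequence nucleotide string (A/C/G/T/N).
#' @return Entropy in bits, in \[0, 2\].
#' @export
shannon_entropy <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  b <- strsplit(toupper(sequence), "")[[1]]
  b <- b[b != "N"]
  if (length(b) == 0L) stop("sequence contains only N bases; entropy undefined")
  f <- table(b) / length(b)
  -sum(f * log2(f)) + 0  # + 0 normalizes the IEEE -0 of a homopolymer
}

#' Contig table constructor and FASTA I/O
#'
#' Contigs are modeled as a data frame with columns `id`, `sequence`,
#' `read_support` and derived `entropy` (bits). On disk they are FASTA with
#' the read support encoded as `support=<int>` in the description line.
#'
#' @param id,sequence,read_support per-contig fields.
#' @return A data frame of class `contig_set`.
#' @export
contig_set <- function(id, sequence, read_support) {
  sequence <- toupper(as.character(sequence))
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad)) stop("non-ACGTN base in contig(s): ", paste(id[bad], collapse = ", "))
  structure(data.frame(id = as.character(id), sequence = sequence,
                       read_support = as.integer(read_support),
                       entropy = vapply(sequence, shannon_entropy, numeric(1),
                                        USE.NAMES = FALSE),
                       stringsAsFactors = FALSE),
            class = c("contig_set", "data.frame"))
}

#' @rdname contig_set
#' @param path FASTA path; headers carry `support=<int>`.
#' @export
read_contig_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  sup <- suppressWarnings(as.integer(sub(".*support=([0-9]+).*", "\\1", hdr)))
  if (anyNA(sup))
    stop("missing 'support=<int>' in contig header(s): ",
         paste(id[is.na(sup)], collapse = ", "))
  contig_set(id, as.character(seqs), sup)
}

#' @rdname contig_set
#' @param contigs a `contig_set`.
#' @export
write_contig_fasta <- function(contigs, path) {
  writeLines(paste0(">", contigs$id, " support=", contigs$read_support, "\n",
                    contigs$sequence), path)
  invisible(path)
}

#' Filter contigs on length, read support, and entropy
#'
#' Retains contigs at least `min_len` bp long and supported by at least
#' `min_support` reads (both inclusive, "at least"), with entropy at least
#' `min_entropy` bits to exclude homopolymer-like assemblies.
#'
#' @param contigs a [contig_set()].
#' @param min_len minimum length, bp (inclusive; default 100).
#' @param min_support minimum read support (inclusive; default 20).
#' @param min_entropy minimum composition entropy, bits (default 1.0; real
#'   viral sequence sits near 1.9, homopolymers at 0).
#' @return The surviving contigs.
#' @export
filter_contigs <- function(contigs, min_len = 100, min_support = 20,
                           min_entropy = 1.0) {
  keep <- nchar(contigs$sequence) >= min_len &
    contigs$read_support >= min_support &
    contigs$entropy >= min_entropy
  contigs[keep, , drop = FALSE]
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

GENCODE <- Biostrings::GENETIC_CODE

orfs_in_frame <- function(seq, offset) {
  n <- nchar(seq)
  ncod <- (n - offset + 1) %/% 3
  if (ncod < 2L) return(NULL)
  starts <- offset + 3 * (seq_len(ncod) - 1)
  codons <- substring(seq, starts, starts + 2)
  aa <- GENCODE[codons]
  aa[is.na(aa)] <- "X"  # codons containing N break reading
  out <- list()
  seg_start <- 1L
  i <- 1L
  while (i <= ncod) {
    if (aa[i] == "*" || aa[i] == "X") {
      if (aa[i] == "*") {
        # longest ORF ending at this stop: first ATG in the open segment
        atg <- which(codons[seg_start:(i - 1)] == "ATG")
        if (i > seg_start && length(atg)) {
          a <- seg_start + atg[1] - 1L
          out[[length(out) + 1L]] <-
            list(cstart = a, cstop = i,
                 protein = paste(aa[a:(i - 1L)], collapse = ""))
        }
      }
      seg_start <- i + 1L
    }
    i <- i + 1L
  }
  if (!length(out)) return(NULL)
  data.frame(start = vapply(out, function(o) starts[o$cstart], numeric(1)),
             end = vapply(out, function(o) starts[o$cstop] + 2, numeric(1)),
             protein = vapply(out, `[[`, character(1), "protein"))
}

#' Six-frame open reading frame extraction
#'
#' Scans all six reading frames of a contig for ORFs (`ATG` ... stop; the
#' stop codon is excluded from the protein but included in the nucleotide
#' span) and reports proteins of at least `min_aa` residues. Nested ORFs
#' sharing a stop codon report only the longest. Reverse-strand ORFs are
#' mapped back to forward-strand coordinates.
#'
#' @param sequence nucleotide string, or a single-row [contig_set()].
#' @param min_aa minimum protein length in residues (default 100; a preset
#'   of 300 reproduces a stricter excision of short products).
#' @param contig_id identifier carried into the output.
#' @return A data frame of class `orf_calls`: `contig_id`, `frame` (+1..+3,
#'   -1..-3), `start`, `end` (1-based inclusive, forward strand), `protein`.
#' @export
find_orfs <- function(sequence, min_aa = 100, contig_id = "contig") {
  if (is.data.frame(sequence)) {
    contig_id <- sequence$id[1]
    sequence <- sequence$sequence[1]
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  res <- list()
  for (off in 1:3) {
    fr <- orfs_in_frame(sequence, off)
    if (!is.null(fr)) {
      fr$frame <- off
      res[[length(res) + 1L]] <- fr
    }
  }
  rc <- revcomp(sequence)
  for (off in 1:3) {
    fr <- orfs_in_frame(rc, off)
    if (!is.null(fr)) {
      # reflect reverse-complement coordinates onto the forward strand
      s <- n - fr$end + 1
      e <- n - fr$start + 1
      fr$start <- s; fr$end <- e
      fr$frame <- -off
      res[[length(res) + 1L]] <- fr
    }
  }
  empty <- data.frame(contig_id = character(0), frame = integer(0),
                      start = numeric(0), end = numeric(0),
                      protein = character(0))
  if (!length(res)) return(structure(empty, class = c("orf_calls", "data.frame")))
  out <- do.call(rbind, res)
  out <- out[nchar(out$protein) >= min_aa, , drop = FALSE]
  if (!nrow(out)) return(structure(empty, class = c("orf_calls", "data.frame")))
  out$contig_id <- contig_id
  out <- out[order(out$start, out$end, out$frame),
             c("contig_id", "frame", "start", "end", "protein")]
  rownames(out) <- NULL
  structure(out, class = c("orf_calls", "data.frame"))
}
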