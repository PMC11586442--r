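# Fixture builders shared across test files. Everything is generated in
# code; no data files.

BASES4 <- c("A", "C", "G", "T")

# Pileup from an L x 4 count matrix (columns A/C/G/T).
make_pileup <- function(counts, ref = "chr1") {
  colnames(counts) <- BASES4
  structure(list(ref = ref, counts = counts), class = "calc_pileup")
}

# Pileup whose positions all carry `depth` reads of the reference base.
uniform_pileup <- function(seq_chars, depth = 10L, ref = "chr1") {
  L <- length(seq_chars)
  cnt <- matrix(0L, L, 4, dimnames = list(NULL, BASES4))
  cnt[cbind(seq_len(L), match(seq_chars, BASES4))] <- as.integer(depth)
  make_pileup(cnt, ref)
}

# Hand-built alignment table (one row per read).
make_aln <- function(start, seq, tlen = NULL, qid = NULL, strand = NULL,
                     qual = NULL, mask = 0L, ref_len = 100L,
                     ref_id = "chr1") {
  n <- length(start)
  len <- nchar(seq)
  aln <- data.frame(
    qid = qid %||% seq_len(n),
    start = as.integer(start), len = len,
    strand = strand %||% rep("+", n),
    seq = seq,
    qual = qual %||% strrep("F", len),
    tlen = as.integer(tlen %||% pmax(len, 100L)),
    mask = as.integer(mask), stringsAsFactors = FALSE)
  structure(aln, class = c("calc_alignments", "data.frame"),
            ref_id = ref_id, ref_len = as.integer(ref_len))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force codon-effect oracle, independent of the implementation:
# translation via seqinr, enumeration over all codons/positions/alternatives.
oracle_effect <- function(codon, pos, alt) {
  tr <- function(cod) seqinr::translate(strsplit(cod, "")[[1]])
  alt_codon <- codon
  substr(alt_codon, pos, pos) <- alt
  if (tr(codon) == tr(alt_codon)) "synonymous" else "nonsynonymous"
}
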