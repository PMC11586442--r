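#' Read-simulation configuration
#'
#' Paired-end fragments are drawn uniformly over the genome; fragment
#' (insert/template) lengths follow a truncated log-normal. Read length is
#' \code{min(read_length, fragment)} so short ancient fragments yield fully
#' overlapping mate pairs, which is what makes mate-overlap deduplication
#' and the minimum-insert filter meaningful downstream. With the default
#' \code{insert_min = read_length} every read is exactly \code{read_length}
#' bases (a point-mass read-length distribution); passing a vector to
#' \code{read_length} samples per-pair lengths from that empirical list.
#'
#' @param seed RNG seed (mandatory).
#' @param n_pairs number of read pairs; alternatively give \code{depth}.
#' @param depth target mean coverage, converted to \code{n_pairs} at
#'   simulation time from the genome length.
#' @param read_length sequencing cycles (single value) or an empirical list
#'   of lengths sampled per pair.
#' @param insert_meanlog,insert_sdlog log-normal parameters of the fragment
#'   length distribution.
#' @param insert_min,insert_max truncation bounds for fragment length;
#'   \code{insert_min = NULL} defaults to \code{max(read_length)} so that
#'   proper pairs satisfy insert >= read length.
#' @param damage a \code{\link{damage_profile}}.
#' @return a \code{sim_config} object.
#' @export
sim_config <- function(seed, n_pairs = NULL, depth = NULL, read_length = 75,
                       insert_meanlog = log(120), insert_sdlog = 0.35,
                       insert_min = NULL, insert_max = 400,
                       damage = damage_profile("none")) {
  if (missing(seed)) stop("sim_config requires a seed")
  if (is.null(n_pairs) && is.null(depth))
    stop("give n_pairs or depth")
  stopifnot(inherits(damage, "damage_profile"), all(read_length >= 1))
  insert_min <- insert_min %||% max(read_length)
  structure(list(seed = as.integer(seed), n_pairs = n_pairs, depth = depth,
                 read_length = as.integer(read_length),
                 insert_meanlog = insert_meanlog, insert_sdlog = insert_sdlog,
                 insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max), damage = damage),
            class = "sim_config")
}

#' Simulate damaged paired-end read alignments from a genome
#'
#' Fragments are placed uniformly; both mates are recorded with their true
#' alignment coordinates, so no aligner is involved. Deamination is applied
#' in read orientation per the damage profile -- C>T decaying from each
#' read's 5' end and the mirrored G>A from its 3' end -- and sequences are
#' stored in reference orientation (as in SAM). In reference orientation
#' this is equivalent, for either strand, to C>T at the alignment's left
#' end and G>A at its right end with the same positional rates, which is
#' the property the empirical damage-rate tests check.
#'
#' @param genome a \code{calc_genome}.
#' @param config a \code{\link{sim_config}}.
#' @return a \code{calc_alignments} data.frame (one row per read) with
#'   attributes \code{ref_id} and \code{ref_len}. Columns: \code{qid} (pair
#'   id), \code{start} (1-based leftmost), \code{len}, \code{strand},
#'   \code{seq} (reference orientation), \code{qual} (phred+33 string,
#'   constant Q37), \code{tlen} (signed template length), \code{mask}.
#' @export
simulate_reads <- function(genome, config) {
  stopifnot(inherits(genome, "calc_genome"), inherits(config, "sim_config"))
  L <- nchar(genome$sequence)
  if (L == 0) stop("empty genome")
  n <- config$n_pairs %||%
    ceiling(L * config$depth / (2 * mean(config$read_length)))
  with_seed(config$seed, {
    rl <- if (length(config$read_length) > 1)
      sample(config$read_length, n, replace = TRUE)
    else rep.int(config$read_length, n)
    lo <- pmax(config$insert_min, rl)
    frag <- round(stats::rlnorm(n, config$insert_meanlog, config$insert_sdlog))
    frag <- pmin(pmax(frag, lo), config$insert_max)
    frag <- pmin(frag, L)  # genome shorter than insert_max guard
    start <- floor(stats::runif(n) * (L - frag + 1)) + 1L
    len1 <- pmin(rl, frag)
    len2 <- len1
    ## mate 1 forward from fragment start; mate 2 reverse from fragment end
    s1 <- start
    s2 <- start + frag - len2
    starts <- c(s1, s2)
    lens <- c(len1, len2)
    strands <- rep(c("+", "-"), each = n)
    tlens <- c(frag, -frag)
    qid <- rep.int(seq_len(n), 2L)
    seqs <- substring(genome$sequence, starts, starts + lens - 1L)
    seqs <- apply_damage(seqs, lens, config$damage)
    aln <- data.frame(qid = qid, start = starts, len = lens,
                      strand = strands, seq = seqs,
                      qual = strrep("F", lens), tlen = tlens,
                      mask = 0L, stringsAsFactors = FALSE)
    structure(aln, class = c("calc_alignments", "data.frame"),
              ref_id = genome$id, ref_len = L)
  })
}

## Vectorized deamination on reference-orientation sequences: C>T with
## rate(d_left) and G>A with rate(d_right), equivalent to read-orientation
## 5' C>T / 3' G>A for both strands. Consumes RNG (call under with_seed).
apply_damage <- function(seqs, lens, profile) {
  if (profile$d0 == 0 || profile$extent == 0) return(seqs)
  total <- sum(lens)
  ridx <- rep.int(seq_along(seqs), lens)
  dL <- sequence(lens) - 1L
  dR <- lens[ridx] - 1L - dL
  base <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  u <- stats::runif(total)
  flipC <- base == "C" & u < damage_rate(profile, dL)
  flipG <- base == "G" & u < damage_rate(profile, dR)
  hit <- which(flipC | flipG)
  if (!length(hit)) return(seqs)
  newb <- ifelse(flipC[hit], "T", "A")
  ri <- ridx[hit]
  off <- dL[hit] + 1L
  ## vectorized substr<- cannot write twice into one element; apply in
  ## rounds where read indices are unique
  round_id <- stats::ave(seq_along(ri), ri, FUN = seq_along)
  for (r in unique(round_id)) {
    k <- round_id == r
    s <- seqs[ri[k]]
    substr(s, off[k], off[k]) <- newb[k]
    seqs[ri[k]] <- s
  }
  seqs
}

#' Write alignments as SAM text
#'
#' Emits a minimal valid SAM: \code{@HD}/\code{@SQ} header, 1-based POS,
#' proper-pair FLAGs (99/147), CIGAR \code{<len>M}, signed TLEN, and a
#' \code{XU:Z:} tag carrying the UDG class when present.
#'
#' @param aln a \code{calc_alignments} data.frame.
#' @param path output file.
#' @param udg_class optional UDG class recorded as an XU tag.
#' @export
write_sam <- function(aln, path, udg_class = NULL) {
  ref <- attr(aln, "ref_id") %||% "chr1"
  L <- attr(aln, "ref_len")
  stopifnot(!is.null(L))
  fwd <- aln$strand == "+"
  flag <- ifelse(fwd, 99L, 147L)
  qname <- sprintf("pair_%06d", aln$qid)
  pnext <- integer(nrow(aln))
  ## mate's leftmost position: for the forward mate it is start + |tlen| - mate len;
  ## with equal mate lengths this is symmetric
  pnext[fwd] <- aln$start[fwd] + abs(aln$tlen[fwd]) - aln$len[fwd]
  pnext[!fwd] <- aln$start[!fwd] - abs(aln$tlen[!fwd]) + aln$len[!fwd]
  tag <- if (is.null(udg_class)) "" else paste0("\tXU:Z:", udg_class)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s%s",
                   qname, flag, ref, aln$start, aln$len, pnext, aln$tlen,
                   aln$seq, aln$qual, tag)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", ref, L)), con)
  writeLines(lines, con)
  invisible(path)
}

#' Read SAM text emitted by this package (or any coordinate-true SAM with
#' ungapped \code{<len>M} alignments)
#'
#' @param path SAM file.
#' @return a \code{calc_alignments} data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (!length(sq)) stop("SAM lacks @SQ header")
  ref_id <- sub("^.*SN:([^\t]+).*$", "\\1", sq[1])
  ref_len <- as.integer(sub("^.*LN:([0-9]+).*$", "\\1", sq[1]))
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- as.integer(vapply(f, `[`, "", 2))
  seqs <- vapply(f, `[`, "", 10)
  qname <- vapply(f, `[`, "", 1)
  aln <- data.frame(
    qid = match(qname, unique(qname)),
    start = as.integer(vapply(f, `[`, "", 4)),
    len = nchar(seqs),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    seq = seqs,
    qual = vapply(f, `[`, "", 11),
    tlen = as.integer(vapply(f, `[`, "", 9)),
    mask = 0L, stringsAsFactors = FALSE)
  structure(aln, class = c("calc_alignments", "data.frame"),
            ref_id = ref_id, ref_len = ref_len)
}
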