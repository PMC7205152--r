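# Fixtures are built in code at test time: a tiny reference FASTA, SAM
# records converted to BAM via Rsamtools, hand-made RD profiles, and
# independent oracles for TV denoising, 1-D two-means and forest paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- reference + alignment fixtures ---------------------------------------

# deterministic pseudo-random ACGT sequence with an optional N run
refSequence <- function(len, nRun = NULL, seed = 99L) {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (!is.null(nRun)) s[nRun] <- "N"
  paste(s, collapse = "")
}

writeRefFasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  xs <- Biostrings::DNAStringSet(unlist(seqs))
  names(xs) <- names(seqs)
  Biostrings::writeXStringSet(xs, path)
  path
}

# reads: data.frame(rname, pos, flag); produces a sorted, indexed BAM
writeBam <- function(reads, contigs,
                     dir = withr::local_tempdir(.local_envir = parent.frame()),
                     readLen = 100L) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contigs),
                   unname(unlist(contigs))))
  body <- character(0)
  if (nrow(reads)) {
    reads <- reads[order(reads$rname, reads$pos), ]
    seq <- strrep("A", readLen)
    body <- sprintf("r%04d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                    seq_len(nrow(reads)), reads$flag, reads$rname,
                    reads$pos, readLen, seq)
  }
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

simpleReads <- function(rname, pos, flag = 0L) {
  data.frame(rname = rep(rname, length.out = length(pos)), pos = pos,
             flag = rep(flag, length.out = length(pos)))
}

# ---- profile fixture built through the public TSV route -------------------

makeProfile <- function(rd, gc = rep(0.5, length(rd)),
                        masked = rep(FALSE, length(rd)),
                        chrom = rep("chrT", length(rd)), binSize = 1000L) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  # chrom must arrive in contiguous blocks; bins are consecutive per chrom
  idx <- stats::ave(seq_along(rd), chrom, FUN = seq_along) - 1L
  df <- data.frame(chrom = chrom, start = idx * binSize,
                   end = (idx + 1L) * binSize, gc = gc, n_frac = 0,
                   rd_raw = rd, rd_corrected = rd,
                   masked = as.integer(masked))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  readRDProfile(path)
}

# ---- independent oracles ---------------------------------------------------

# TV proximal problem solved by projected gradient on the dual
#   min_{|z_i|<=lam} 0.5 * || y - D' z ||^2 ,  x = y - D' z
# a genuinely different algorithm from the direct taut-string solver
tvOracle <- function(y, lam, iters = 50000L) {
  n <- length(y)
  if (n <= 1L || lam == 0) return(y)
  z <- numeric(n - 1L)
  Dt <- function(z) c(-z, 0) + c(0, z)         # D' z
  D <- function(x) diff(x)                     # not used; clarity
  for (k in seq_len(iters)) {
    x <- y - Dt(z)
    g <- -diff(x)                              # gradient D (D'z - y)
    z <- pmin(lam, pmax(-lam, z - 0.25 * g))
  }
  y - Dt(z)
}

totalVariation <- function(x) sum(abs(diff(x)))

# brute-force exact two-means: scan every sorted-threshold partition
wcssOracle <- function(Q) {
  o <- order(Q); qs <- Q[o]; n <- length(qs)
  wcss <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  best <- Inf; bestT <- 1L
  for (t in seq_len(n - 1L)) {
    w <- wcss(qs[1:t]) + wcss(qs[(t + 1):n])
    if (w < best - 1e-12) { best <- w; bestT <- t }
  }
  labels <- integer(n)
  labels[o] <- rep(c(0L, 1L), c(bestT, n - bestT))
  list(labels = labels, wcss = best)
}

wcssOf <- function(Q, labels) {
  sum(unlist(lapply(split(Q, labels), function(v)
    if (length(v) <= 1) 0 else sum((v - mean(v))^2))))
}

# recursive walk of a fitted isolation tree's nested node structure
treePathOracle <- function(node, x, depth = 0) {
  if (node$leaf)
    return(depth + if (node$size <= 1) 0
           else 2 * (log(node$size - 1) + 0.5772156649015329) -
                2 * (node$size - 1) / node$size)
  if (x < node$split) treePathOracle(node$left, x, depth + 1)
  else treePathOracle(node$right, x, depth + 1)
}

forestScoreOracle <- function(forest, xs) {
  cf <- 2 * (log(forest$subsample - 1) + 0.5772156649015329) -
        2 * (forest$subsample - 1) / forest$subsample
  vapply(xs, function(x) {
    h <- mean(vapply(forest$trees,
                     function(tr) treePathOracle(tr$root, x), numeric(1)))
    2^(-h / cf)
  }, numeric(1))
}

# noiseless loss-region RDs planted at purity alpha0 (independent
# arithmetic, not via expectedRD)
noiselessLossRD <- function(alpha0, rBar, nHom, nHet) {
  c(rep((1 - alpha0) * rBar, nHom), rep((1 - alpha0 / 2) * rBar, nHet))
}
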