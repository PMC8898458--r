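# Synthetic genomes and bins with exact ground truth. Genomes are sampled
# from seeded order-2 Markov chains with per-context transition
# probabilities drawn from a Dirichlet distribution tilted towards a GC
# target: low Dirichlet concentration gives compositionally distinctive
# genomes, which is precisely the signal the k-mer signatures detect. Bins
# are cut from these genomes with recorded per-contig provenance, so their
# completeness and purity are known exactly rather than estimated.

#' Simulate a compositionally distinctive genome
#'
#' Samples a DNA sequence from an order-`markov_order` Markov chain. The
#' transition probabilities of each context are drawn from a Dirichlet
#' distribution with parameters `4 * concentration * w`, where `w` puts
#' weight `gc_target/2` on G and C and `(1 - gc_target)/2` on A and T, so
#' the expected GC content equals `gc_target` while smaller `concentration`
#' values yield stronger (more genome-specific) compositional biases.
#'
#' @param length Sequence length in bp, at least 10 kb.
#' @param markov_order Order of the chain (default 2).
#' @param concentration Dirichlet concentration, `> 0`; smaller is more
#'   distinctive.
#' @param gc_target Expected GC fraction.
#' @param seed Integer seed; the same parameters and seed regenerate the
#'   identical sequence.
#' @param id Genome identifier.
#' @return A list of class `synthetic_genome` with `id`, `sequence`,
#'   `length` and the generator parameters.
#' @export
simulate_genome <- function(length, markov_order = 2L, concentration = 0.5,
                            gc_target = 0.5, seed = 1L, id = "genome") {
  stopifnot(length >= 10000L, concentration > 0,
            gc_target > 0, gc_target < 1, markov_order >= 1L)
  n <- as.integer(length)
  set.seed(as.integer(seed))
  n_ctx <- 4L^markov_order
  w <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
         (1 - gc_target) / 2)
  alpha <- 4 * concentration * w
  P <- matrix(stats::rgamma(n_ctx * 4L, shape = rep(alpha, each = n_ctx)),
              n_ctx, 4L)
  P <- P / rowSums(P)
  # pin the conditional GC probability of every context to the target, so
  # realized GC concentrates tightly around gc_target; distinctiveness
  # lives in the within-class (A vs T, C vs G) and context structure
  at <- pmax(P[, 1L] + P[, 4L], 1e-12)
  gc <- pmax(P[, 2L] + P[, 3L], 1e-12)
  P[, c(1L, 4L)] <- P[, c(1L, 4L)] / at * (1 - gc_target)
  P[, c(2L, 3L)] <- P[, c(2L, 3L)] / gc * gc_target
  cum <- t(apply(P, 1L, cumsum))
  cp1 <- cum[, 1L]; cp2 <- cum[, 2L]; cp3 <- cum[, 3L]
  u <- stats::runif(n)
  out <- integer(n)
  ctx <- sample.int(n_ctx, 1L)
  mod <- as.integer(n_ctx / 4L)
  for (i in seq_len(n)) {
    ui <- u[i]
    b <- 1L + (ui > cp1[ctx]) + (ui > cp2[ctx]) + (ui > cp3[ctx])
    out[i] <- b
    ctx <- ((ctx - 1L) %% mod) * 4L + b
  }
  structure(list(id = id,
                 sequence = paste(c("A", "C", "G", "T")[out], collapse = ""),
                 length = n,
                 params = list(markov_order = as.integer(markov_order),
                               concentration = concentration,
                               gc_target = gc_target,
                               seed = as.integer(seed))),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome", x$id, "-", x$length, "bp, GC target",
      x$params$gc_target, "\n")
  invisible(x)
}

# Cut a contiguous region [from, from+total) of a genome into contigs with
# log-normal lengths; returns a data.frame of contig records with
# provenance intervals (0-based half-open).
cut_contigs <- function(genome, from, total, meanlog, sdlog, prefix,
                        min_contig = 150L) {
  seqs <- character(); ids <- character()
  starts <- integer(); ends <- integer()
  pos <- from
  left <- total
  k <- 0L
  while (left >= min_contig) {
    len <- max(min_contig, round(stats::rlnorm(1L, meanlog, sdlog)))
    if (len > left - min_contig) len <- left  # absorb the remainder
    k <- k + 1L
    ids <- c(ids, sprintf("%s_c%03d", prefix, k))
    seqs <- c(seqs, substring(genome$sequence, pos + 1L, pos + len))
    starts <- c(starts, pos); ends <- c(ends, pos + len)
    pos <- pos + len
    left <- left - len
  }
  data.frame(contig_id = ids, genome_id = genome$id, start = starts,
             end = ends, sequence = seqs, stringsAsFactors = FALSE)
}

#' Simulate a bin with known completeness and purity
#'
#' Cuts contigs from a contiguous, randomly placed region of the source
#' genome totalling `target_completeness` of its length, then appends
#' contaminant contigs cut from the other genomes until the bin's purity is
#' close to `target_purity`. Contaminant base pairs are spread over enough
#' genomes that the source always remains the best-matching genome. Contig
#' lengths are log-normal (`meanlog`/`sdlog`, default median 10 kb). The
#' realized completeness and purity are recorded exactly from the per-contig
#' provenance; they differ from the targets by at most rounding and the
#' minimum contig length.
#'
#' @param source A `synthetic_genome`.
#' @param contaminants List of `synthetic_genome`s (may be empty when
#'   `target_purity = 1`).
#' @param target_completeness,target_purity Targets in `(0, 1]`.
#' @param meanlog,sdlog Log-normal contig-length parameters.
#' @param seed Integer seed.
#' @param id Bin identifier.
#' @return A list of class `synthetic_bin`: `bin` (a [mag_bin]),
#'   `truth` (a `bin_truth`), and `provenance` (per-contig genome and
#'   interval).
#' @export
simulate_bin <- function(source, contaminants = list(),
                         target_completeness = 1, target_purity = 1,
                         meanlog = log(10000), sdlog = 0.6,
                         seed = 1L, id = "bin") {
  stopifnot(target_completeness > 0, target_completeness <= 1,
            target_purity > 0, target_purity <= 1)
  set.seed(as.integer(seed))
  G <- source$length
  M <- max(500L, round(target_completeness * G))
  M <- min(M, G)
  from <- if (M == G) 0L else sample.int(G - M + 1L, 1L) - 1L
  prov <- cut_contigs(source, from, M, meanlog, sdlog, paste0(id, "_src"))
  matching <- sum(prov$end - prov$start)
  C_target <- round(matching * (1 / target_purity - 1))
  if (C_target > 0) {
    if (length(contaminants) == 0L)
      stop("infeasible targets: purity < 1 requires contaminant genomes")
    # spread contamination over as many genomes as needed so that every
    # contaminant stays strictly below the source's base-pair share
    picks <- contaminants[sample.int(length(contaminants))]
    remaining <- C_target
    for (cg in picks) {
      if (remaining < 150L) break
      take <- min(remaining, floor(0.9 * matching), cg$length)
      if (take < 150L) break
      offs <- sample.int(cg$length - take + 1L, 1L) - 1L
      prov <- rbind(prov,
                    cut_contigs(cg, offs, take, meanlog, sdlog,
                                paste0(id, "_", cg$id)))
      remaining <- remaining - take
    }
    if (remaining >= 0.5 * C_target && C_target >= 150L)
      stop("infeasible targets: not enough contaminant material")
  }
  bin <- mag_bin(id, stats::setNames(prov$sequence, prov$contig_id))
  sizes <- stats::setNames(
    vapply(c(list(source), contaminants), `[[`, 0L, "length"),
    vapply(c(list(source), contaminants), `[[`, "", "id"))
  truth <- gold_standard(bin, stats::setNames(prov$genome_id, prov$contig_id),
                         sizes)
  if (truth$best_genome != source$id)
    stop("contamination exceeded the source genome; lower the target purity spread")
  structure(list(bin = bin, truth = truth,
                 provenance = prov[c("contig_id", "genome_id", "start", "end")]),
            class = "synthetic_bin")
}

#' Simulate a labelled bin dataset
#'
#' Generates `n_genomes` compositionally distinct genomes (GC targets spread
#' over `gc_range`, lengths uniform over `genome_length_range`) and
#' `n_bins` bins whose completeness and purity targets are drawn uniformly
#' over the given ranges. Source genomes rotate over the genome panel, and
#' each bin's contaminants are drawn from the remaining genomes. All
#' randomness derives from the single root `seed`; the same call is
#' byte-reproducible. Optionally writes the bins as FASTA files plus a
#' truth TSV.
#'
#' @param n_genomes Number of genomes, at least 5.
#' @param n_bins Number of bins, at least 30.
#' @param completeness_range,purity_range Target ranges (fractions).
#' @param genome_length_range Genome lengths in bp.
#' @param gc_range Range of genome GC targets.
#' @param concentration Dirichlet concentration of the genome chains.
#' @param meanlog,sdlog Contig-length log-normal parameters (default
#'   median 5 kb, matching the scaled fragment lengths of [desk_config()]).
#' @param contig_median_range Optional: when given, each bin draws its own
#'   median contig length log-uniformly from this range instead of using
#'   `meanlog`, emulating assemblies of varying fragmentation.
#' @param seed Root seed.
#' @param out_dir Optional directory; writes `bins/<bin>.fasta`,
#'   `truth.tsv` and `genomes.fasta`.
#' @return List with `bins` (list of [mag_bin]), `truth` (data frame
#'   `bin_id`, `best_genome`, `completeness`, `purity`, `f1`), `genomes`,
#'   and `provenance`.
#' @export
simulate_dataset <- function(n_genomes = 20L, n_bins = 200L,
                             completeness_range = c(0.2, 1),
                             purity_range = c(0.3, 1),
                             genome_length_range = c(200000L, 500000L),
                             gc_range = c(0.3, 0.7),
                             concentration = 0.5,
                             meanlog = log(5000), sdlog = 0.6,
                             contig_median_range = NULL,
                             seed = 1L, out_dir = NULL) {
  stopifnot(n_genomes >= 5L, n_bins >= 30L)
  set.seed(as.integer(seed))
  glens <- sample(seq(genome_length_range[1L], genome_length_range[2L]),
                  n_genomes, replace = TRUE)
  gcs <- seq(gc_range[1L], gc_range[2L], length.out = n_genomes)
  gseeds <- sample.int(2^30, n_genomes)
  bseeds <- sample.int(2^30, n_bins)
  tc <- stats::runif(n_bins, completeness_range[1L], completeness_range[2L])
  tp <- stats::runif(n_bins, purity_range[1L], purity_range[2L])
  medlog <- if (is.null(contig_median_range)) rep(meanlog, n_bins) else
    stats::runif(n_bins, log(contig_median_range[1L]),
                 log(contig_median_range[2L]))
  src_idx <- rep_len(seq_len(n_genomes), n_bins)
  genomes <- lapply(seq_len(n_genomes), function(i)
    simulate_genome(glens[i], concentration = concentration,
                    gc_target = gcs[i], seed = gseeds[i],
                    id = sprintf("g%02d", i)))
  bins <- vector("list", n_bins)
  truth <- vector("list", n_bins)
  prov <- vector("list", n_bins)
  for (b in seq_len(n_bins)) {
    sb <- simulate_bin(genomes[[src_idx[b]]],
                       contaminants = genomes[-src_idx[b]],
                       target_completeness = tc[b], target_purity = tp[b],
                       meanlog = medlog[b], sdlog = sdlog,
                       seed = bseeds[b], id = sprintf("bin%03d", b))
    bins[[b]] <- sb$bin
    truth[[b]] <- data.frame(bin_id = sb$truth$bin_id,
                             best_genome = sb$truth$best_genome,
                             completeness = sb$truth$completeness,
                             purity = sb$truth$purity,
                             f1 = sb$truth$f1, stringsAsFactors = FALSE)
    prov[[b]] <- sb$provenance
  }
  names(bins) <- vapply(bins, `[[`, "", "id")
  res <- list(bins = bins, truth = do.call(rbind, truth),
              genomes = genomes, provenance = do.call(rbind, prov))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "bins"), recursive = TRUE,
               showWarnings = FALSE)
    for (b in bins) write_bin_fasta(b, file.path(out_dir, "bins",
                                                 paste0(b$id, ".fasta")))
    utils::write.table(res$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    con <- file(file.path(out_dir, "genomes.fasta"), "wb")
    for (g in genomes)
      writeLines(c(paste0(">", g$id), wrap_seq(g$sequence)), con, sep = "\n")
    close(con)
  }
  res
}

wrap_seq <- function(s, width = 70L) {
  substring(s, seq(1L, nchar(s), width),
            pmin(seq(width, nchar(s) + width - 1L, width), nchar(s)))
}

#' Write one bin as a FASTA file
#'
#' Plain 70-column FASTA, byte-deterministic.
#'
#' @param bin A [mag_bin].
#' @param path Output path.
#' @export
write_bin_fasta <- function(bin, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(bin$contigs)))
    writeLines(c(paste0(">", bin$contigs$id[i]),
                 wrap_seq(bin$contigs$sequence[i])), con, sep = "\n")
  invisible(path)
}
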