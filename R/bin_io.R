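#' Construct a bin from contig sequences
#'
#' @param id Bin identifier.
#' @param sequences Character vector (or `DNAStringSet`) of contig sequences;
#'   names are used as contig ids, otherwise `contig_1..n`. Sequences are
#'   uppercased and characters outside A/C/G/T/N are mapped to N.
#' @return An object of class `mag_bin`: a list with `id`, a `contigs`
#'   data frame (`id`, `sequence`, `length`) and `size_bp`.
#' @export
mag_bin <- function(id, sequences) {
  ids <- names(sequences)
  seqs <- as.character(sequences)
  if (length(seqs) == 0L) stop("bin contains no contigs: ", id)
  if (any(nchar(seqs) == 0L))
    stop("zero-length contig in bin: ", id)
  seqs <- gsub("[^ACGTN]", "N", toupper(seqs))  # drops names
  if (is.null(ids) || any(ids == "")) ids <- paste0("contig_", seq_along(seqs))
  ids <- sub("\\s.*$", "", ids)  # FASTA description after first whitespace
  if (anyDuplicated(ids))
    stop("duplicated contig ids in bin: ", id)
  contigs <- data.frame(id = ids, sequence = unname(seqs),
                        length = nchar(seqs), stringsAsFactors = FALSE)
  structure(list(id = id, contigs = contigs,
                 size_bp = sum(contigs$length)),
            class = "mag_bin")
}

#' @export
print.mag_bin <- function(x, ...) {
  cat("mag_bin", x$id, "-", nrow(x$contigs), "contigs,",
      x$size_bp, "bp (longest", max(x$contigs$length), "bp)\n")
  invisible(x)
}

#' Read bins from FASTA files
#'
#' Each FASTA file is one bin; the bin id is the file stem. Gzip-compressed
#' files are accepted. Sequences are uppercased and ambiguity codes other
#' than N are mapped to N.
#'
#' @param path A FASTA file, a vector of FASTA files, or a directory
#'   containing them (`.fa`, `.fasta`, `.fna`, optionally `.gz`).
#' @return A named list of [mag_bin] objects.
#' @export
read_bins <- function(path) {
  if (length(path) == 1L && dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(fa|fasta|fna)(\\.gz)?$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("no FASTA files found in ", path)
  } else {
    files <- path
  }
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("file not found: ", missing[1])
  bins <- lapply(files, function(f) {
    dss <- tryCatch(Biostrings::readDNAStringSet(f),
                    error = function(e)
                      stop("malformed FASTA file ", f, ": ",
                           conditionMessage(e), call. = FALSE))
    if (length(dss) == 0L) stop("bin contains no contigs: ", f)
    if (any(Biostrings::width(dss) == 0L))
      stop("zero-length record in ", f)
    stem <- tools::file_path_sans_ext(basename(f))
    if (grepl("\\.(fa|fasta|fna)$", stem))
      stem <- tools::file_path_sans_ext(stem)  # strip .fasta under .gz
    seqs <- as.character(dss)
    mag_bin(stem, seqs)
  })
  names(bins) <- vapply(bins, `[[`, "", "id")
  if (anyDuplicated(names(bins))) stop("duplicate bin ids among input files")
  bins
}

#' Cut contigs into fixed-length fragments
#'
#' Fragments start at 0, `step`, `2*step`, ... on each contig while the full
#' fragment fits; the trailing remainder is discarded, and fragments never
#' span contigs. Fragments with less than `min_acgt_frac` unambiguous bases
#' are dropped.
#'
#' @param bin A [mag_bin].
#' @param fragment_length Fragment length in bp.
#' @param step Start-to-start distance in bp (defaults to non-overlapping).
#' @param min_acgt_frac Minimum fraction of A/C/G/T per fragment.
#' @return A data frame with columns `bin_id`, `contig_id`, `start`
#'   (0-based), `length`, `sequence`; zero rows if nothing qualifies.
#' @export
fragment_contigs <- function(bin, fragment_length, step = fragment_length,
                             min_acgt_frac = 0.9) {
  stopifnot(fragment_length >= 1L, step >= 1L, step <= fragment_length)
  L <- as.integer(fragment_length)
  empty <- data.frame(bin_id = character(), contig_id = character(),
                      start = integer(), length = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  keep <- bin$contigs$length >= L
  if (!any(keep)) return(empty)
  pieces <- lapply(which(keep), function(i) {
    clen <- bin$contigs$length[i]
    starts <- seq.int(0L, clen - L, by = step)
    data.frame(bin_id = bin$id,
               contig_id = bin$contigs$id[i],
               start = starts,
               length = L,
               sequence = substring(bin$contigs$sequence[i],
                                    starts + 1L, starts + L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  acgt <- Biostrings::letterFrequency(
    Biostrings::DNAStringSet(out$sequence), letters = "ACGT")
  out <- out[acgt / L >= min_acgt_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Number of fragments a bin yields at length L with non-overlapping steps,
# after the ambiguity filter.
n_fragments_at <- function(bin, L, min_acgt_frac = 0.9) {
  nrow(fragment_contigs(bin, L, min_acgt_frac = min_acgt_frac))
}

#' Bin eligibility and model tier
#'
#' A bin is eligible when it contains at least one contig longer than twice
#' the GC fragment length, or at least two contigs longer than the GC
#' fragment length (with the default 1 kb GC fragments: one contig > 2 kb or
#' multiple contigs > 1 kb). The tier is the largest configured fragment
#' length at which the bin still yields at least three non-overlapping
#' fragments (two for the smallest, GC-only tier).
#'
#' @param bin A [mag_bin].
#' @param config A [magqc_config()].
#' @return A list with `eligible` (logical) and `tier` (integer fragment
#'   length in bp, or `NA` when not eligible).
#' @export
bin_eligibility <- function(bin, config = magqc_config()) {
  gc_len <- config$fragment_lengths[["gc"]]
  eligible <- any(bin$contigs$length > 2L * gc_len) ||
    sum(bin$contigs$length > gc_len) >= 2L
  tier <- NA_integer_
  if (eligible) {
    tiers <- config_tiers(config)
    smallest <- min(tiers)
    for (L in tiers) {
      need <- if (L == smallest) 2L else 3L
      if (n_fragments_at(bin, L, config$min_acgt_frac) >= need) {
        tier <- L
        break
      }
    }
    if (is.na(tier)) eligible <- FALSE
  }
  list(eligible = eligible, tier = tier)
}
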