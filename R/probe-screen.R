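DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(seq, NULL), function(ch)
    paste(rev(ch), collapse = ""), character(1)))
}

check_dna <- function(seq) {
  if (any(grepl("[^ACGTN]", seq))) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(seq)
}

#' Tile hybridization probes along a target sequence
#'
#' Left-greedy maximal tiling of `probe_length`-nt probes with at least
#' `min_gap` nt between adjacent probes (defaults 20 nt and 2 nt, the
#' standard smFISH design geometry), capped at `max_probes` oligos. Each
#' probe is the reverse complement of its target window, ready to hybridize
#' the mRNA.
#'
#' @param target Target sequence (sense strand, A/C/G/T).
#' @param probe_length Probe length in nt (default 20).
#' @param min_gap Minimum inter-probe gap in nt (default 2).
#' @param max_probes Cap on the number of probes (default 48).
#' @return A tibble: `probe_id`, `start` (0-based position on the target),
#'   `target_window`, `sequence` (the probe, reverse-complementary to the
#'   window). Zero rows (with a warning) if the target is too short.
#' @examples
#' tile_probes(paste(rep("ACGT", 11), collapse = ""))  # 44 nt -> 2 probes
#' @export
tile_probes <- function(target, probe_length = 20L, min_gap = 2L,
                        max_probes = 48L) {
  target <- toupper(target)
  check_dna(target)
  L <- nchar(target)
  if (L < probe_length) {
    warning("target shorter than one probe (", L, " nt)", call. = FALSE)
    return(tibble::tibble(probe_id = character(0), start = integer(0),
                          target_window = character(0), sequence = character(0)))
  }
  starts <- integer(0)
  pos <- 0L
  while (pos + probe_length <= L && length(starts) < max_probes) {
    starts <- c(starts, pos)
    pos <- pos + probe_length + min_gap
  }
  windows <- substring(target, starts + 1L, starts + probe_length)
  tibble::tibble(
    probe_id = sprintf("probe_%02d", seq_along(starts)),
    start = starts,
    target_window = windows,
    sequence = revcomp(windows)
  )
}

#' Off-target screening of probes by exhaustive Hamming scan
#'
#' For each probe, finds the best (fewest-mismatch) ungapped alignment
#' against every non-target transcript, on both strands, by exhaustive
#' sliding-window Hamming comparison. A probe is excluded when its best
#' off-target hit has at most `max_mismatch` mismatches (default 3, i.e.
#' >= 17/20 identity): such near-perfect complementarity elsewhere in the
#' transcriptome is an off-target binding risk.
#'
#' @param probes Tibble from [tile_probes()] (needs `probe_id`, `sequence`).
#' @param transcriptome Named character vector or `Biostrings::DNAStringSet`
#'   of transcript sense sequences.
#' @param target_id Name(s) of the target transcript(s) to skip during
#'   screening.
#' @param max_mismatch Exclusion threshold on the best off-target hit
#'   (default 3).
#' @return A list: `kept` and `excluded` tibbles; both carry
#'   `best_mismatches`, `best_transcript` and `best_position` hit evidence
#'   (NA when no alignment with < probe-length mismatches exists).
#' @export
offtarget_filter <- function(probes, transcriptome, target_id = character(0),
                             max_mismatch = 3L) {
  if (inherits(transcriptome, "DNAStringSet")) {
    transcriptome <- setNames(as.character(transcriptome), names(transcriptome))
  }
  transcriptome <- toupper(transcriptome)
  check_dna(transcriptome)
  if (length(transcriptome) == 0L) {
    stop("transcriptome must be non-empty", call. = FALSE)
  }
  others <- transcriptome[!(names(transcriptome) %in% target_id)]
  if (length(others) == 0L) {
    out <- dplyr::mutate(probes, best_mismatches = NA_integer_,
                         best_transcript = NA_character_,
                         best_position = NA_integer_, excluded = FALSE)
    return(list(kept = out, excluded = out[0, ]))
  }
  # a probe binds an off-target mRNA when the mRNA sense sequence is
  # near-complementary to the probe: scan the probe's reverse complement
  # (sense-strand match) and the probe itself (antisense transcripts)
  fwd <- hamming_scan_cpp(revcomp(probes$sequence), unname(others))
  rev <- hamming_scan_cpp(probes$sequence, unname(others))
  use_fwd <- is.na(rev$best_mismatches) |
    (!is.na(fwd$best_mismatches) & fwd$best_mismatches <= rev$best_mismatches)
  best <- ifelse(use_fwd, fwd$best_mismatches, rev$best_mismatches)
  subj <- ifelse(use_fwd, fwd$subject_index, rev$subject_index)
  pos <- ifelse(use_fwd, fwd$position, rev$position)
  out <- dplyr::mutate(
    probes,
    best_mismatches = as.integer(best),
    best_transcript = names(others)[subj],
    best_position = as.integer(pos),
    excluded = !is.na(best) & best <= max_mismatch
  )
  list(kept = out[!out$excluded, , drop = FALSE],
       excluded = out[out$excluded, , drop = FALSE])
}

strip_polya <- function(seq, min_run = 10L) {
  m <- regmatches(seq, regexpr("A+$", seq))
  if (length(m) == 1L && nchar(m) >= min_run) {
    substr(seq, 1L, nchar(seq) - nchar(m))
  } else {
    seq
  }
}

# count of 20-mer windows of `seq` with a <= max_mm mismatch hit in `other`
# (either strand), windows taken every `stride` nt
shared_window_count <- function(seq, other, window = 20L, max_mm = 3L,
                                stride = 5L) {
  L <- nchar(seq)
  if (L < window) return(0L)
  starts <- seq(1L, L - window + 1L, by = stride)
  wins <- substring(seq, starts, starts + window - 1L)
  hits <- hamming_scan_cpp(wins, other)$best_mismatches
  hits_rc <- hamming_scan_cpp(revcomp(wins), other)$best_mismatches
  best <- pmin(ifelse(is.na(hits), window, hits),
               ifelse(is.na(hits_rc), window, hits_rc))
  sum(best <= max_mm)
}

# longest run of positions (on the first isoform) whose 20-mer occurs
# exactly in every isoform
common_exonic_run <- function(isoforms, window = 20L) {
  ref <- isoforms[[1]]
  L <- nchar(ref)
  if (L < window || length(isoforms) == 1L) return(L)
  starts <- seq_len(L - window + 1L)
  wins <- substring(ref, starts, starts + window - 1L)
  shared <- rep(TRUE, length(starts))
  for (iso in isoforms[-1]) {
    kmers <- substring(iso, seq_len(max(0L, nchar(iso) - window + 1L)),
                       seq_len(max(0L, nchar(iso) - window + 1L)) + window - 1L)
    shared <- shared & (wins %in% kmers)
  }
  if (!any(shared)) return(0L)
  r <- rle(shared)
  best <- max(r$lengths[r$values])
  best + window - 1L  # run of window starts -> covered nucleotides
}

#' Screen a candidate reference gene for probe-set suitability
#'
#' Evaluates the reference-gene selection criteria: (i) transcript longer
#' than 700 nt excluding the polyA tail (trailing A-run of >= 10 stripped);
#' (ii) distinctness from paralogues/pseudogenes -- no more than
#' `max_shared_windows` 20-nt windows with >= 85% identity (<= 3 mismatches)
#' anywhere in another family member, either strand; (iii) at most
#' `max_isoforms` transcript variants; (iv) a common exonic region shared by
#' all isoforms large enough to host at least `min_probes` tiled probes.
#'
#' @param record List with `gene_id` and `isoforms` (character vector of
#'   transcript sequences, primary first).
#' @param gene_family List of similar records for related genes (may be
#'   empty).
#' @param min_length Criterion (i) threshold in nt (default 700).
#' @param max_shared_windows Criterion (ii) tolerance (default 5).
#' @param max_isoforms Criterion (iii) threshold (default 3).
#' @param min_probes Criterion (iv) probe capacity (default 43).
#' @return A list of class `screen_report`: `gene_id`, `pass` (overall),
#'   `criteria` tibble (criterion, pass, detail), `common_run_nt`.
#' @export
screen_gene <- function(record, gene_family = list(), min_length = 700L,
                        max_shared_windows = 5L, max_isoforms = 3L,
                        min_probes = 43L) {
  stopifnot(!is.null(record$gene_id), length(record$isoforms) >= 1L)
  isoforms <- toupper(record$isoforms)
  check_dna(isoforms)
  primary <- strip_polya(isoforms[[1]])

  len_ok <- nchar(primary) > min_length
  len_detail <- sprintf("%d nt after polyA stripping (need > %d)",
                        nchar(primary), min_length)

  fam <- gene_family[vapply(gene_family, function(r) r$gene_id != record$gene_id,
                            logical(1))]
  shared <- if (length(fam) == 0L) 0L else {
    max(vapply(fam, function(r) {
      shared_window_count(primary, toupper(r$isoforms))
    }, numeric(1)))
  }
  dist_ok <- shared <= max_shared_windows
  dist_detail <- sprintf("max %d near-identical 20-nt windows vs family (allow <= %d)",
                         shared, max_shared_windows)

  iso_ok <- length(isoforms) <= max_isoforms
  iso_detail <- sprintf("%d isoform(s) (allow <= %d)", length(isoforms),
                        max_isoforms)

  run <- common_exonic_run(isoforms)
  capacity <- if (run >= 20L) nrow(tile_probes(strrep("A", run),
                                               max_probes = .Machine$integer.max)) else 0L
  cov_ok <- capacity >= min_probes
  cov_detail <- sprintf("common exonic run %d nt hosts %d probes (need >= %d)",
                        run, capacity, min_probes)

  criteria <- tibble::tibble(
    criterion = c("length_gt_700", "paralogue_distinct", "few_isoforms",
                  "common_exon_coverage"),
    pass = c(len_ok, dist_ok, iso_ok, cov_ok),
    detail = c(len_detail, dist_detail, iso_detail, cov_detail)
  )
  structure(
    list(gene_id = record$gene_id, pass = all(criteria$pass),
         criteria = criteria, common_run_nt = run,
         reasons = criteria$detail[!criteria$pass]),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %s: %s\n", x$gene_id,
              if (x$pass) "PASS" else "FAIL"))
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  [%s] %-22s %s\n",
                if (x$criteria$pass[i]) "ok" else "FAIL",
                x$criteria$criterion[i], x$criteria$detail[i]))
  }
  invisible(x)
}

#' Read transcript sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning a named
#' character vector suitable for [offtarget_filter()] and [screen_gene()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).
#' @export
read_transcripts <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
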