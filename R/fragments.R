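# The 20 standard amino acids, one-letter codes, alphabetical by code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from a FASTA file
#'
#' Sequences are validated against the 20 standard one-letter residue
#' symbols; any other character (including `X`, `B`, `U`, `*` or gaps)
#' is a hard error naming the offending record.
#'
#' @param fasta Path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences; names are the first
#'   whitespace-delimited token of each FASTA header.
#' @export
read_proteins <- function(fasta) {
  set <- Biostrings::readAAStringSet(fasta)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein IDs in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  for (id in names(seqs)) validate_sequence(seqs[[id]], id)
  seqs
}

validate_sequence <- function(sequence, id = "<unnamed>") {
  if (!nzchar(sequence)) stop("empty sequence for protein '", id, "'")
  chars <- unique(strsplit(sequence, "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, AA20)
  if (length(bad))
    stop("non-standard residue(s) ", paste(bad, collapse = ", "),
         " in protein '", id, "'")
  invisible(TRUE)
}

#' Load candidate sites and join them to their proteins
#'
#' Reads a tab-separated site table with columns `protein_id`, `position`
#' (1-based) and optionally `label` (1 = modified, 0 = unmodified), checks
#' each row against the FASTA sequences, and keeps rows whose position
#' carries a lysine. Rows pointing at a non-K residue are dropped with a
#' warning; an unknown protein ID or an out-of-bounds position is an error.
#'
#' @param fasta Path to a FASTA file (or a named character vector of
#'   already-validated sequences).
#' @param sites Path to a TSV site table, or a data frame with the same
#'   columns.
#' @return A data frame with columns `protein_id`, `position`, `label`
#'   (integer or `NA` for unknown).
#' @export
load_sites <- function(fasta, sites) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta))
    read_proteins(fasta) else fasta
  if (is.null(names(seqs))) stop("sequences must be named by protein ID")
  tab <- if (is.data.frame(sites)) sites else
    utils::read.delim(sites, header = TRUE, stringsAsFactors = FALSE)
  req <- c("protein_id", "position")
  if (!all(req %in% names(tab)))
    stop("site table must have columns: ", paste(req, collapse = ", "))
  if (is.null(tab$label)) tab$label <- NA_integer_
  tab$position <- as.integer(tab$position)
  tab$label <- as.integer(tab$label)

  missing_ids <- setdiff(unique(tab$protein_id), names(seqs))
  if (length(missing_ids))
    stop("site table references protein ID(s) absent from FASTA: ",
         paste(missing_ids, collapse = ", "))
  lens <- nchar(seqs)[tab$protein_id]
  oob <- tab$position < 1L | tab$position > lens
  if (any(oob))
    stop("site position out of sequence bounds for: ",
         paste(sprintf("%s:%d", tab$protein_id[oob], tab$position[oob]),
               collapse = ", "))
  res <- substr(seqs[tab$protein_id], tab$position, tab$position)
  not_k <- res != "K"
  if (any(not_k)) {
    warning(sum(not_k), " site row(s) point at a non-K residue and were skipped: ",
            paste(utils::head(sprintf("%s:%d(%s)", tab$protein_id[not_k],
                                      tab$position[not_k], res[not_k]), 5L),
                  collapse = ", "))
    tab <- tab[!not_k, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[c("protein_id", "position", "label")]
}

#' Extract a fixed-length fragment around a lysine with mirror extension
#'
#' Builds the window of `2 * flank + 1` residues centred on the candidate
#' K (signed offsets `-flank ... +flank`, offset 0 = the K). Offsets that
#' fall outside the protein are filled by reflection across the central K:
#' a missing offset `-i` takes the residue at `+i` and vice versa. When
#' the protein is so short that some offsets are missing on both sides
#' even after reflection, the already-filled core (a palindrome around K)
#' is mirrored outward repeatedly until the window is complete, which
#' preserves the reflection identity `residues[-i] == residues[+i]` for
#' every filled pair.
#'
#' @param sequence Protein sequence (string over the 20 standard residues).
#' @param site_pos 1-based position of the candidate K in `sequence`.
#' @param flank Number of residues on each side of the K (default 25,
#'   giving 51-mers).
#' @return Character scalar of length `2 * flank + 1`.
#' @export
mirror_extend <- function(sequence, site_pos, flank = 25L) {
  n <- nchar(sequence)
  if (site_pos < 1L || site_pos > n) stop("site_pos out of bounds")
  if (substr(sequence, site_pos, site_pos) != "K")
    stop("residue at site_pos is not K")
  if (n < 3L)
    stop("protein has fewer than 2 residues besides the candidate K; ",
         "mirror extension impossible")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  offs <- (-flank):flank
  pos <- site_pos + offs
  frag <- rep(NA_character_, length(offs))
  inside <- pos >= 1L & pos <= n
  frag[inside] <- chars[pos[inside]]
  centre <- flank + 1L
  # reflection across the K: fill -i from +i and +i from -i
  for (i in seq_len(flank)) {
    lo <- centre - i; hi <- centre + i
    if (is.na(frag[lo]) && !is.na(frag[hi])) frag[lo] <- frag[hi]
    if (is.na(frag[hi]) && !is.na(frag[lo])) frag[hi] <- frag[lo]
  }
  # protein shorter than the window on both sides: mirror the filled
  # palindromic core outward until the window is complete
  m <- max(which(!is.na(frag[centre:(2L * flank + 1L)]))) - 1L
  if (m < flank) {
    fold <- function(i) {        # reflect i into [-m, m] across the core edges
      while (i > m || i < -m) {
        if (i > m) i <- 2L * m - i
        if (i < -m) i <- -2L * m - i
      }
      abs(i)                      # core is a palindrome: f(-j) == f(j)
    }
    for (i in (m + 1L):flank) {
      frag[centre + i] <- frag[centre + fold(i)]
      frag[centre - i] <- frag[centre + i]
    }
  }
  paste(frag, collapse = "")
}

#' Build labelled site fragments from proteins and a site table
#'
#' @param seqs Named character vector of protein sequences.
#' @param sites Data frame as returned by [load_sites()].
#' @inheritParams mirror_extend
#' @return A data frame of class `chidt_fragments` with columns
#'   `protein_id`, `position`, `fragment`, `label`, plus attribute `flank`.
#' @export
make_fragments <- function(seqs, sites, flank = 25L) {
  frags <- vapply(seq_len(nrow(sites)), function(i) {
    mirror_extend(seqs[[sites$protein_id[i]]], sites$position[i], flank)
  }, character(1))
  out <- data.frame(protein_id = sites$protein_id,
                    position = sites$position,
                    fragment = frags,
                    label = sites$label,
                    stringsAsFactors = FALSE)
  attr(out, "flank") <- as.integer(flank)
  class(out) <- c("chidt_fragments", class(out))
  out
}

#' Enumerate every lysine in a set of proteins as an unlabelled site table
#'
#' Used for de-novo scanning: each K becomes one candidate row with
#' `label = NA`.
#'
#' @param seqs Named character vector of protein sequences.
#' @return Site table data frame (`protein_id`, `position`, `label`).
#' @export
scan_lysines <- function(seqs) {
  if (is.null(names(seqs))) stop("sequences must be named by protein ID")
  rows <- lapply(names(seqs), function(id) {
    pos <- which(strsplit(seqs[[id]], "", fixed = TRUE)[[1]] == "K")
    if (!length(pos)) return(NULL)
    data.frame(protein_id = id, position = pos, label = NA_integer_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), position = integer(),
                      label = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# n x (2*flank+1) character matrix of fragment residues;
# columns named by signed offset.
fragment_matrix <- function(fragments) {
  flank <- attr(fragments, "flank")
  if (is.null(flank)) flank <- (nchar(fragments$fragment[1]) - 1L) %/% 2L
  mat <- do.call(rbind, strsplit(fragments$fragment, "", fixed = TRUE))
  colnames(mat) <- as.character((-flank):flank)
  mat
}

#' Write fragments to a tab-separated file
#'
#' Columns: `protein_id`, `position`, `fragment`, `label`.
#'
#' @param fragments A `chidt_fragments` data frame.
#' @param path Output file path.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(as.data.frame(fragments)[c("protein_id", "position",
                                                "fragment", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
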