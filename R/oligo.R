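#' Construct a (possibly methylated) RNA oligonucleotide
#'
#' The unit consumed by every mass computation: an RNA sequence over
#' `{A, C, G, U}` with explicit terminal chemistry and a list of positioned
#' base-methyl modifications.  Mature miRNAs carry a 5'-monophosphate and a
#' 3'-hydroxyl, which are the defaults.  Modification positions are 1-based
#' counted from the 5' end.
#'
#' @param seq RNA sequence string over `A`, `C`, `G`, `U` (case-insensitive;
#'   `T` is rejected — this package models RNA chemistry only).
#' @param five_prime 5' terminus: `"phosphate"` (default) or `"hydroxyl"`.
#' @param three_prime 3' terminus: `"hydroxyl"` (default), `"phosphate"`, or
#'   `"cyclic_phosphate"` (2',3'-cyclic phosphate).
#' @param mods Modifications, either a named list/vector mapping positions to
#'   modification ids (`list("13" = "m6A")`), a character vector in the
#'   grammar `"POS:ID[,POS:ID...]"` (e.g. `"13:m6A"`), or `NULL`.
#' @return An object of class `oligo` with fields `seq` (character vector of
#'   bases), `five_prime`, `three_prime`, `mods` (data frame with columns
#'   `position`, `id`).
#' @export
#' @examples
#' oligo("UGAGGUAGUAGGUUGUAUAGUU", mods = "13:m6A")
oligo <- function(seq,
                  five_prime = c("phosphate", "hydroxyl"),
                  three_prime = c("hydroxyl", "phosphate", "cyclic_phosphate"),
                  mods = NULL) {
  five_prime <- match.arg(five_prime)
  three_prime <- match.arg(three_prime)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("`seq` must be a non-empty sequence string", call. = FALSE)
  }
  bases <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(bases), c("A", "C", "G", "U"))
  if (length(bad)) {
    stop("invalid residue character(s): ", paste(bad, collapse = ", "),
         " (RNA alphabet is A, C, G, U)", call. = FALSE)
  }
  mods <- parse_mods(mods)
  n <- length(bases)
  if (nrow(mods)) {
    if (any(mods$position < 1L | mods$position > n)) {
      stop("modification position outside [1, ", n, "]", call. = FALSE)
    }
    if (anyDuplicated(mods$position)) {
      stop("at most one modification per position", call. = FALSE)
    }
    for (i in seq_len(nrow(mods))) {
      parent <- .MODIFICATIONS[[mods$id[i]]]$parent
      have <- bases[mods$position[i]]
      if (have != parent) {
        stop(sprintf("modification %s requires parent base %s but position %d is %s",
                     mods$id[i], parent, mods$position[i], have), call. = FALSE)
      }
    }
    mods <- mods[order(mods$position), , drop = FALSE]
    rownames(mods) <- NULL
  }
  structure(list(seq = bases, five_prime = five_prime,
                 three_prime = three_prime, mods = mods),
            class = "oligo")
}

#' Parse a modification specification
#'
#' Accepts the CLI grammar `"POS:ID[,POS:ID...]"`, a named list/vector
#' (`list("13" = "m6A")`), a data frame with columns `position` and `id`,
#' or `NULL` (no modifications).
#'
#' @param mods Specification as above.
#' @return Data frame with integer column `position` and character `id`.
#' @export
parse_mods <- function(mods) {
  empty <- data.frame(position = integer(), id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(mods) || (is.character(mods) && length(mods) == 1L && !nzchar(mods))) {
    return(empty)
  }
  if (is.data.frame(mods)) {
    stopifnot(all(c("position", "id") %in% names(mods)))
    out <- data.frame(position = as.integer(mods$position),
                      id = as.character(mods$id), stringsAsFactors = FALSE)
  } else if (is.character(mods) && is.null(names(mods)) && length(mods) == 1L) {
    parts <- strsplit(mods, ",", fixed = TRUE)[[1]]
    kv <- strsplit(trimws(parts), ":", fixed = TRUE)
    if (any(lengths(kv) != 2L)) {
      stop("modification spec must follow POS:ID[,POS:ID...]", call. = FALSE)
    }
    out <- data.frame(position = as.integer(vapply(kv, `[`, "", 1L)),
                      id = vapply(kv, `[`, "", 2L), stringsAsFactors = FALSE)
  } else {
    out <- data.frame(position = as.integer(names(mods)),
                      id = as.character(unlist(mods)), stringsAsFactors = FALSE)
  }
  if (any(is.na(out$position))) {
    stop("modification positions must be integers", call. = FALSE)
  }
  bad <- setdiff(out$id, names(.MODIFICATIONS))
  if (length(bad)) {
    stop("unknown modification id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' @export
print.oligo <- function(x, ...) {
  cat(sprintf("<oligo> 5'-%s %s 3'-%s (%d nt)\n",
              x$five_prime, paste(x$seq, collapse = ""), x$three_prime,
              length(x$seq)))
  if (nrow(x$mods)) {
    cat("  mods: ",
        paste(sprintf("%d:%s", x$mods$position, x$mods$id), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.oligo <- function(x) length(x$seq)

#' Read mature miRNA sequences from a FASTA file
#'
#' Thin reader for mature-miRNA FASTA (e.g. a miRBase extract).  `T` is
#' transcribed to `U` so DNA-alphabet copies of mature sequences also load.
#'
#' @param path FASTA file.
#' @param id Optional record id; when given, returns that single sequence
#'   string, otherwise a named character vector of all records.
#' @return Named character vector of RNA sequences, or a single string.
#' @export
read_mirna_fasta <- function(path, id = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- gsub("T", "U", toupper(as.character(set)), fixed = TRUE)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
  if (!is.null(id)) {
    if (!id %in% names(seqs)) stop("id '", id, "' not found in ", path,
                                   call. = FALSE)
    return(unname(seqs[[id]]))
  }
  seqs
}
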