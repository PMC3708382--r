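## Alignment container and FASTA / relaxed sequential PHYLIP I/O.

#' Construct an alignment object
#'
#' The package-wide alignment container: a character matrix (taxa in rows,
#' sites in columns) over a 4-state DNA or 20-state amino-acid alphabet,
#' plus gap (`-`) and ambiguity (`N` for DNA, `X` for amino acids) codes.
#' Characters outside the alphabet are mapped to the ambiguity code with a
#' warning; gaps and ambiguities are treated as missing data downstream.
#'
#' @param mat character matrix with unique rownames (taxon labels).
#' @param alphabet `"dna"` or `"aa"`.
#' @return object of class `pi_alignment`.
#' @export
pi_alignment <- function(mat, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.matrix(mat), is.character(mat))
  labels <- rownames(mat)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("alignment rows must carry non-empty taxon labels")
  if (anyDuplicated(labels))
    stop("duplicate taxon labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  mat[] <- toupper(mat)
  states <- if (alphabet == "dna") DNA_STATES else AA_STATES
  amb <- if (alphabet == "dna") "N" else "X"
  ok <- mat %in% c(states, amb, "-")
  if (!all(ok)) {
    warning(sum(!ok), " character(s) outside the ", alphabet,
            " alphabet mapped to ambiguity code '", amb, "'")
    mat[!ok] <- amb
  }
  structure(mat, alphabet = alphabet, class = "pi_alignment")
}

#' @export
print.pi_alignment <- function(x, ...) {
  cat(sprintf("<pi_alignment> %d taxa x %d sites (%s)\n",
              nrow(x), ncol(x), attr(x, "alphabet")))
  invisible(x)
}

#' @export
`[.pi_alignment` <- function(x, i, j, ...) {
  m <- unclass(x)
  attr(m, "alphabet") <- NULL
  pi_alignment(m[i, j, drop = FALSE], attr(x, "alphabet"))
}

alignment_alphabet <- function(aln) attr(aln, "alphabet")

## integer-coded matrix: 1..n_states, NA for gap/ambiguity
alignment_codes <- function(aln) {
  states <- if (attr(aln, "alphabet") == "dna") DNA_STATES else AA_STATES
  m <- match(unclass(aln), states)
  dim(m) <- dim(aln)
  rownames(m) <- rownames(aln)
  m
}

guess_alphabet <- function(chars) {
  u <- setdiff(unique(toupper(chars)), c("-", "N", "X"))
  if (length(u) && all(u %in% DNA_STATES)) "dna" else "aa"
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA or relaxed sequential PHYLIP (labels separated from the
#' sequence by whitespace; sequence may continue on following lines).
#' Sequences must be equal length and labels unique.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @param alphabet `"auto"` (default), `"dna"` or `"aa"`.
#' @return a [pi_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           alphabet = c("auto", "dna", "aa")) {
  format <- match.arg(format)
  alphabet <- match.arg(alphabet)
  lines <- readLines(path)
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (!length(hdr)) stop("no FASTA headers found in ", path)
    labels <- sub("^>\\s*", "", lines[hdr])
    labels <- sub("\\s.*$", "", labels)
    ends <- c(hdr[-1] - 1L, length(lines))
    seqs <- vapply(seq_along(hdr), function(i) {
      block <- lines[seq(hdr[i] + 1L, ends[i])]
      gsub("\\s", "", paste(block, collapse = ""))
    }, character(1))
  } else {
    lines <- lines[nzchar(trimws(lines))]
    head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n <- as.integer(head_fields[1]); m <- as.integer(head_fields[2])
    if (is.na(n) || is.na(m)) stop("malformed PHYLIP header in ", path)
    body <- lines[-1]
    labels <- character(n); seqs <- character(n)
    i <- 1L
    for (k in seq_len(n)) {
      fields <- strsplit(trimws(body[i]), "\\s+")[[1]]
      labels[k] <- fields[1]
      s <- paste(fields[-1], collapse = "")
      i <- i + 1L
      while (nchar(s) < m) {
        if (i > length(body)) stop("PHYLIP sequence for '", labels[k],
                                   "' shorter than declared length ", m)
        s <- paste0(s, gsub("\\s", "", body[i]))
        i <- i + 1L
      }
      seqs[k] <- s
    }
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences have unequal lengths; offending taxa: ",
         paste(labels[lens != stats::median(lens)], collapse = ", "))
  chars <- strsplit(seqs, "")
  mat <- do.call(rbind, chars)
  rownames(mat) <- labels
  if (alphabet == "auto") alphabet <- guess_alphabet(mat)
  pi_alignment(mat, alphabet)
}

#' Write an alignment
#'
#' @param aln a [pi_alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"phylip"` (relaxed sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  seqs <- apply(unclass(aln), 1, paste, collapse = "")
  labels <- rownames(aln)
  if (format == "fasta") {
    chunks <- lapply(seqs, function(s)
      substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59, nchar(s))))
    out <- unlist(mapply(function(l, ch) c(paste0(">", l), ch),
                         labels, chunks, SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    out <- c(paste(nrow(aln), ncol(aln)),
             paste(format(labels, width = max(nchar(labels))), seqs))
  }
  writeLines(out, path)
  invisible(path)
}
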