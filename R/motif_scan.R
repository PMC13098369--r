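#' Registry of the root TF's binding elements
#'
#' The three promoter elements the root bZIP TF binds, as established by
#' TF-centered yeast one-hybrid deletion/mutation series:
#' \itemize{
#'   \item GATA-box — isolated as `ATGATAAGG`; no degenerate positions were
#'     established, so its core is the full 9-mer.
#'   \item TGGT-box — isolated as `GTGGTGG`; core `TGGT` (offset 2) whose
#'     first base tolerates `C`, giving the degenerate core `[C/T]GGT`.
#'   \item GGAT-box — isolated as `GGGGATG`; core `GGAT` (offset 3) with no
#'     substitutions tolerated at any position.
#' }
#'
#' @param gata_core `"full"` (default; match the whole 9-mer) or `"gata"`
#'   (match only the 4-mer `GATA`), since no deletion series bounded the
#'   GATA-box core.
#' @return list of `element_definition` objects with fields `id`,
#'   `full_sequence`, `core` (list of allowed-base sets per position) and
#'   `core_offset` (1-based start of the core inside the full site).
#' @export
#' @examples
#' length(element_registry())  # 3
element_registry <- function(gata_core = c("full", "gata")) {
  gata_core <- match.arg(gata_core)
  def <- function(id, full, core, offset) {
    structure(list(id = id, full_sequence = full, core = core,
                   core_offset = offset),
              class = "element_definition")
  }
  exact <- function(s) lapply(strsplit(s, "")[[1]], identity)
  gata <- if (gata_core == "full") {
    def("GATA-box", "ATGATAAGG", exact("ATGATAAGG"), 1L)
  } else {
    def("GATA-box", "ATGATAAGG", exact("GATA"), 3L)
  }
  list(
    gata,
    def("TGGT-box", "GTGGTGG",
        c(list(c("C", "T")), exact("GGT")), 2L),
    def("GGAT-box", "GGGGATG", exact("GGAT"), 3L)
  )
}

#' @export
print.element_definition <- function(x, ...) {
  core <- paste(vapply(x$core, function(b) {
    if (length(b) == 1) b else sprintf("[%s]", paste(b, collapse = "/"))
  }, ""), collapse = "")
  cat(sprintf("%s: full site %s, core %s at offset %d\n",
              x$id, x$full_sequence, core, x$core_offset))
  invisible(x)
}

# degenerate core -> IUPAC pattern string for Biostrings matching
.core_pattern <- function(element) {
  iupac <- names(Biostrings::IUPAC_CODE_MAP)
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(element$core, function(allowed) {
    code <- paste(sort(allowed), collapse = "")
    iupac[match(code, vapply(map, function(x)
      paste(sort(strsplit(x, "")[[1]]), collapse = ""), ""))]
  }, ""), collapse = "")
}

#' Scan a sequence for occurrences of one binding element core
#'
#' Reports every position (overlapping occurrences included) where the
#' element's degenerate core matches. Minus-strand hits are found by scanning
#' the reverse complement and mapping offsets back to plus-strand
#' coordinates; `N` bases never match. Matching is case-insensitive.
#'
#' @param seq a single DNA string (character or [Biostrings::DNAString]) over
#'   `A`, `C`, `G`, `T`, `N`.
#' @param element an `element_definition` from [element_registry()].
#' @param strands `"both"` (default) or `"forward"`.
#' @return data.frame of hits sorted by offset then strand: `element`,
#'   `strand`, `offset` (1-based start on the + strand), `matched` (the
#'   strand-resolved matched bases).
#' @export
#' @examples
#' scan_sequence("GTGGTGG", element_registry()[[2]], strands = "forward")
scan_sequence <- function(seq, element, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(element, "element_definition"))
  s <- toupper(as.character(seq))
  if (grepl("[^ACGTN]", s)) {
    stop("illegal character in sequence (allowed: A, C, G, T, N)")
  }
  subject <- Biostrings::DNAString(s)
  pattern <- .core_pattern(element)
  L <- nchar(pattern)
  hit_df <- function(starts, strand, src) {
    if (!length(starts)) return(NULL)
    if (strand == "+") {
      offs <- starts
      matched <- substring(s, starts, starts + L - 1L)
    } else {
      offs <- nchar(s) - (starts + L - 1L) + 1L
      rc <- as.character(src)
      matched <- substring(rc, starts, starts + L - 1L)
    }
    data.frame(element = element$id, strand = strand, offset = offs,
               matched = matched, stringsAsFactors = FALSE)
  }
  # fixed = "subject": IUPAC degeneracy active in the pattern only, so an N
  # in the subject matches nothing
  fwd <- Biostrings::start(
    Biostrings::matchPattern(pattern, subject, fixed = "subject"))
  out <- list(hit_df(fwd, "+", subject))
  if (strands == "both") {
    rc <- Biostrings::reverseComplement(subject)
    rev <- Biostrings::start(
      Biostrings::matchPattern(pattern, rc, fixed = "subject"))
    out <- c(out, list(hit_df(rev, "-", rc)))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(element = character(), strand = character(),
                      offset = integer(), matched = character())
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Element presence/position table over promoter fragments
#'
#' Scans each promoter fragment for each element and labels it `p+` (element
#' present) or `p-` (absent), the convention used for truncated-promoter
#' ChIP constructs. Hits are reported in fragment-local coordinates; a hit
#' spanning two fragments is not reported here (only whole-promoter scanning
#' sees it).
#'
#' @param fragments data.frame from [fragment_promoter()] (columns `index`,
#'   `sequence`, ...).
#' @param elements list of `element_definition`s (default: full registry).
#' @param strands `"both"` or `"forward"`.
#' @return list with `table` — one row per (fragment, element) with `present`
#'   and `label` (`p+`/`p-`) — and `hits`, the per-fragment hit data.frame
#'   with a `fragment_index` column.
#' @export
elements_in_fragments <- function(fragments, elements = element_registry(),
                                  strands = c("both", "forward")) {
  strands <- match.arg(strands)
  rows <- list(); hits <- list()
  for (i in seq_len(nrow(fragments))) {
    for (el in elements) {
      h <- scan_sequence(fragments$sequence[i], el, strands = strands)
      present <- nrow(h) > 0
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_index = fragments$index[i], element = el$id,
        present = present, label = if (present) "p+" else "p-",
        n_hits = nrow(h), stringsAsFactors = FALSE)
      if (present) {
        h$fragment_index <- fragments$index[i]
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(element = character(), strand = character(),
               offset = integer(), matched = character(),
               fragment_index = integer())
  list(table = do.call(rbind, rows), hits = hits)
}
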