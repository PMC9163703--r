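# Candidate-site enumeration under trypsin-like specificity.
# Schechter-Berger convention throughout: P1 is the residue N-terminal to the
# scissile bond, P2 sits at P1 - 1; protease subsites S1, S2, ... accommodate them.

#' Construct a substrate sequence with author numbering
#'
#' @param identifier free-text name.
#' @param residues one-letter amino-acid string (canonical codes only).
#' @param start_number author number of the first residue.
#' @return an object of class `substrate_sequence`.
#' @export
substrate_sequence <- function(identifier, residues, start_number = 1L) {
  residues <- toupper(residues)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", residues))
    stop("residues must be canonical one-letter amino-acid codes")
  structure(list(identifier = identifier, residues = residues,
                 start_number = as.integer(start_number)),
            class = "substrate_sequence")
}

#' Read substrate sequences from a FASTA file
#'
#' The author number of the first residue can be encoded in the FASTA header
#' as `name/start` (e.g. `>gamma-ENaC/134`) or passed explicitly.
#'
#' @param path FASTA file.
#' @param start_number first-residue author number; overrides any header value.
#' @return a list of `substrate_sequence`.
#' @export
read_substrate_fasta <- function(path, start_number = NULL) {
  fa <- bio3d::read.fasta(path)
  out <- list()
  for (i in seq_len(nrow(fa$ali))) {
    id <- rownames(fa$ali)[i]
    seqstr <- paste(fa$ali[i, fa$ali[i, ] != "-"], collapse = "")
    sn <- start_number
    if (is.null(sn)) {
      m <- regmatches(id, regexec("/([0-9]+)$", id))[[1]]
      sn <- if (length(m) == 2L) as.integer(m[2]) else 1L
    }
    out[[i]] <- substrate_sequence(id, toupper(seqstr), sn)
  }
  out
}

#' @export
print.substrate_sequence <- function(x, ...) {
  end <- x$start_number + nchar(x$residues) - 1L
  cat("Substrate '", x$identifier, "' (", x$start_number, "-", end, "):\n  ",
      x$residues, "\n", sep = "")
  invisible(x)
}

.residue_at <- function(seq, position) {
  idx <- position - seq$start_number + 1L
  if (idx < 1L || idx > nchar(seq$residues)) return(NA_character_)
  substr(seq$residues, idx, idx)
}

.subseq <- function(seq, from, to) {
  i <- from - seq$start_number + 1L
  j <- to - seq$start_number + 1L
  substr(seq$residues, max(1L, i), min(nchar(seq$residues), j))
}

#' Trypsin-like specificity rules
#'
#' Defaults encode TMPRSS2's reported preferences: Arg or Lys at P1, with
#' Arg preferred over Lys, and Lys forbidden at P2 (a K at P2 is incompatible
#' with cleavage). The P1 preference only annotates and breaks ties in site
#' ranking; it never excludes Lys sites.
#'
#' @param p1_allowed residue set accepted at P1.
#' @param p1_preference_order tie-break order at P1.
#' @param p2_forbidden residue set that excludes a site when found at P2.
#' @param rule_provenance citation text carried into reports.
#' @return an object of class `specificity_rules`.
#' @export
specificity_rules <- function(p1_allowed = c("R", "K"),
                              p1_preference_order = c("R", "K"),
                              p2_forbidden = "K",
                              rule_provenance = "trypsin-like; R>K at P1; no K at P2") {
  stopifnot(length(p1_allowed) >= 1L)
  structure(list(p1_allowed = p1_allowed,
                 p1_preference_order = p1_preference_order,
                 p2_forbidden = p2_forbidden,
                 rule_provenance = rule_provenance),
            class = "specificity_rules")
}

#' Construct a mutant specification
#'
#' @param substitutions data frame with columns `position` (author number),
#'   `from_aa`, `to_aa`.
#' @param label canonical construct name.
#' @export
mutant_spec <- function(substitutions, label = NA_character_) {
  stopifnot(is.data.frame(substitutions),
            all(c("position", "from_aa", "to_aa") %in% names(substitutions)))
  if (anyDuplicated(substitutions$position))
    stop("substitution positions must be unique")
  structure(list(substitutions = substitutions, label = label),
            class = "mutant_spec")
}

#' Apply a mutant specification to a substrate sequence
#'
#' Validates every `from_aa` against the wild type before substituting;
#' returns a new sequence, leaving the input unchanged.
#'
#' @param seq a `substrate_sequence`.
#' @param spec a `mutant_spec`.
#' @return a new `substrate_sequence`.
#' @export
apply_mutations <- function(seq, spec) {
  stopifnot(inherits(seq, "substrate_sequence"), inherits(spec, "mutant_spec"))
  residues <- seq$residues
  for (k in seq_len(nrow(spec$substitutions))) {
    s <- spec$substitutions[k, ]
    actual <- .residue_at(seq, s$position)
    if (is.na(actual))
      stop("substitution position ", s$position, " outside sequence span")
    if (actual != s$from_aa)
      stop("wild-type mismatch at ", s$position, ": spec says '", s$from_aa,
           "' but sequence has '", actual, "'")
    idx <- s$position - seq$start_number + 1L
    substr(residues, idx, idx) <- s$to_aa
  }
  lab <- if (is.na(spec$label)) seq$identifier else paste0(seq$identifier, "_", spec$label)
  substrate_sequence(lab, residues, seq$start_number)
}

#' Parse a mutant construct name into a mutant specification
#'
#' Accepts names like `"K168A"`, `"RKRK178AAAA"`, or compounds joined by
#' `";"` or `"+"` (`"RKRR138AAAA + R153A"`). A multi-residue run such as
#' `RKRK178AAAA` carries a single printed position; construct nomenclature
#' anchors it inconsistently (sometimes the first residue of the run,
#' sometimes the last), so both anchorings are tried against the wild-type
#' sequence and the one that matches is used. If both or neither match, the
#' name is ambiguous or wrong and an error names the offending item.
#'
#' @param label construct name.
#' @param seq the wild-type `substrate_sequence` used for validation.
#' @return a `mutant_spec`.
#' @export
parse_mutant_name <- function(label, seq) {
  stopifnot(inherits(seq, "substrate_sequence"))
  items <- trimws(strsplit(label, "[;+]")[[1]])
  items <- items[nzchar(items)]
  if (length(items) == 0L) stop("empty mutant name")
  subs <- list()
  for (item in items) {
    m <- regmatches(item, regexec("^([ACDEFGHIKLMNPQRSTVWY]+)([0-9]+)([ACDEFGHIKLMNPQRSTVWY]+)$", item))[[1]]
    if (length(m) != 4L)
      stop("cannot parse mutant item '", item, "'")
    from <- strsplit(m[2], "")[[1]]
    pos0 <- as.integer(m[3])
    to <- strsplit(m[4], "")[[1]]
    if (length(from) != length(to))
      stop("mutant item '", item, "': wild-type and replacement runs differ in length")
    n <- length(from)
    if (n == 1L) {
      anchors <- list(pos0)
    } else {
      anchors <- list(pos0, pos0 - n + 1L)  # run starts at printed number, or ends there
    }
    ok <- vapply(anchors, function(a) {
      positions <- a + seq_len(n) - 1L
      all(mapply(function(p, f) identical(.residue_at(seq, p), f), positions, from))
    }, logical(1))
    if (sum(ok) == 0L)
      stop("mutant item '", item, "' does not match the wild-type sequence under either run anchoring")
    if (sum(ok) > 1L && length(anchors) > 1L && anchors[[1]] != anchors[[2]])
      stop("mutant item '", item, "' is ambiguous: both run anchorings match the wild-type sequence")
    a <- anchors[[which(ok)[1]]]
    subs[[length(subs) + 1L]] <- data.frame(position = a + seq_len(n) - 1L,
                                            from_aa = from, to_aa = to,
                                            stringsAsFactors = FALSE)
  }
  mutant_spec(do.call(rbind, subs), label = label)
}

#' Regenerate a canonical construct name from a mutant specification
#'
#' Adjacent substituted positions are merged into runs anchored at their
#' first residue; items are joined with `";"`. Round-trips with
#' [parse_mutant_name()] up to anchoring convention.
#'
#' @param spec a `mutant_spec`.
#' @return character name.
#' @export
format_mutant_name <- function(spec) {
  s <- spec$substitutions[order(spec$substitutions$position), , drop = FALSE]
  runs <- cumsum(c(1L, diff(s$position) != 1L))
  items <- vapply(split(seq_len(nrow(s)), runs), function(ix) {
    paste0(paste(s$from_aa[ix], collapse = ""), s$position[ix[1]],
           paste(s$to_aa[ix], collapse = ""))
  }, character(1))
  paste(items, collapse = ";")
}

#' Enumerate candidate P1 cleavage sites in a substrate region
#'
#' Scans the region for residues allowed at P1 (Arg/Lys by default). Each hit
#' becomes one candidate annotated with its P2 residue; candidates whose P2
#' residue is forbidden are retained but flagged excluded, so reports can
#' count all basic residues. The docking window defaults to the 6-mer
#' P4-P2prime (positions P1-3 .. P1+2), truncated with a warning at
#' sequence ends.
#'
#' @param seq a `substrate_sequence`.
#' @param region length-2 author-number interval to scan.
#' @param rules a `specificity_rules`.
#' @param window_policy `"p4_p2prime"` (only policy currently defined).
#' @return data frame of class `cleavage_candidates` with columns
#'   p1_position, p1_residue, p2_residue, excluded, exclusion_reason,
#'   window, window_start, window_end.
#' @export
enumerate_candidates <- function(seq, region, rules = specificity_rules(),
                                 window_policy = "p4_p2prime") {
  stopifnot(inherits(seq, "substrate_sequence"), length(region) == 2L)
  first <- seq$start_number
  last <- seq$start_number + nchar(seq$residues) - 1L
  if (region[1] < first || region[2] > last)
    stop("region ", region[1], "-", region[2], " outside sequence span ",
         first, "-", last)
  rows <- list()
  for (p1 in seq.int(region[1], region[2])) {
    aa <- .residue_at(seq, p1)
    if (!aa %in% rules$p1_allowed) next
    p2 <- .residue_at(seq, p1 - 1L)
    excluded <- !is.na(p2) && p2 %in% rules$p2_forbidden
    reason <- if (excluded) paste0("forbidden residue ", p2, " at P2") else ""
    wstart <- max(first, p1 - 3L)
    wend <- min(last, p1 + 2L)
    if (wstart > p1 - 3L || wend < p1 + 2L)
      warning("window for P1 ", p1, " truncated at sequence end")
    rows[[length(rows) + 1L]] <- data.frame(
      p1_position = p1, p1_residue = aa, p2_residue = ifelse(is.na(p2), "", p2),
      excluded = excluded, exclusion_reason = reason,
      window = .subseq(seq, wstart, wend),
      window_start = wstart, window_end = wend, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(p1_position = integer(), p1_residue = character(),
               p2_residue = character(), excluded = logical(),
               exclusion_reason = character(), window = character(),
               window_start = integer(), window_end = integer(),
               stringsAsFactors = FALSE)
  class(out) <- c("cleavage_candidates", class(out))
  out
}

#' Derive deduplicated 6-mer docking windows from candidates
#'
#' Two policies. `"p1_centered"` emits one P4-P2prime window per candidate
#' (already stored on the candidate table) and deduplicates identical spans.
#' `"region_based"` assigns candidates to caller-supplied literal window
#' anchors (author-number start positions of configured 6-mers), merging
#' candidates that fall in one shared window; candidates falling in no
#' anchor window are dropped with a warning.
#'
#' @param candidates a `cleavage_candidates` table.
#' @param seq the `substrate_sequence` the candidates came from.
#' @param policy `"region_based"` or `"p1_centered"`.
#' @param anchors integer vector of window start positions (region_based only).
#' @param width window width for region_based anchors (default 6).
#' @return data frame with columns window, window_start, window_end,
#'   p1_positions (comma-separated).
#' @export
docking_windows <- function(candidates, seq, policy = c("region_based", "p1_centered"),
                            anchors = NULL, width = 6L) {
  policy <- match.arg(policy)
  if (nrow(candidates) == 0L)
    return(data.frame(window = character(), window_start = integer(),
                      window_end = integer(), p1_positions = character(),
                      stringsAsFactors = FALSE))
  if (policy == "p1_centered") {
    key <- paste(candidates$window_start, candidates$window_end)
    agg <- split(candidates, key)
  } else {
    if (is.null(anchors)) stop("region_based windows require anchor start positions")
    idx <- vapply(candidates$p1_position, function(p) {
      hit <- which(p >= anchors & p <= anchors + width - 1L)
      if (length(hit) == 0L) NA_integer_ else hit[1]
    }, integer(1))
    if (anyNA(idx)) {
      warning("dropping candidate(s) outside all anchor windows: ",
              paste(candidates$p1_position[is.na(idx)], collapse = ", "))
    }
    keep <- !is.na(idx)
    candidates <- candidates[keep, , drop = FALSE]
    candidates$window_start <- anchors[idx[keep]]
    candidates$window_end <- anchors[idx[keep]] + width - 1L
    candidates$window <- vapply(seq_len(nrow(candidates)), function(i)
      .subseq(seq, candidates$window_start[i], candidates$window_end[i]), character(1))
    agg <- split(candidates, paste(candidates$window_start, candidates$window_end))
  }
  out <- do.call(rbind, lapply(agg, function(g) {
    data.frame(window = g$window[1], window_start = g$window_start[1],
               window_end = g$window_end[1],
               p1_positions = paste(sort(g$p1_position), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$window_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a candidate table as TSV
#' @param candidates a `cleavage_candidates` table.
#' @param path output file.
#' @export
write_candidates_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
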