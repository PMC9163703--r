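# Map cleavage events to proteolytic fragments with lengths and unmodified
# average masses. Masses are plain average residue masses (no glycans, no
# disulfides), so they will NOT match apparent molecular weights on a gel;
# reports carry residue spans as the primary identifier.

# average residue (monomer minus water) masses, Da
.AA_AVG_MASS <- c(G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
                  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
                  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
                  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
                  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER_MASS <- 18.0153

#' Unmodified average mass of a peptide
#'
#' Sum of average residue masses plus one water.
#'
#' @param residues one-letter amino-acid string.
#' @return mass in Da.
#' @export
peptide_mass <- function(residues) {
  aa <- strsplit(toupper(residues), "")[[1]]
  if (!all(aa %in% names(.AA_AVG_MASS)))
    stop("non-canonical residue(s): ",
         paste(unique(aa[!aa %in% names(.AA_AVG_MASS)]), collapse = ", "))
  sum(.AA_AVG_MASS[aa]) + .WATER_MASS
}

#' Map cleavage events to proteolytic fragments
#'
#' A cleavage event after author position p cuts the bond between p and p+1.
#' One event yields an N-terminal and a C-terminal fragment; two events yield
#' three fragments, the middle one labelled as the released tract. Fragment
#' spans partition the substrate; each fragment's mass is its residue-mass
#' sum plus one water, so the fragment masses sum to the substrate mass plus
#' one water per cut (hydrolysis adds a water across each cleaved bond).
#'
#' @param seq a `substrate_sequence`.
#' @param events integer vector of 1 or 2 P1 positions (sorted, distinct), or
#'   `integer(0)` for the intact substrate.
#' @return an object of class `fragment_set`: data frame with columns
#'   start, end, length, mass_da, role.
#' @export
fragment_map <- function(seq, events = integer(0)) {
  stopifnot(inherits(seq, "substrate_sequence"), length(events) <= 2L)
  first <- seq$start_number
  last <- seq$start_number + nchar(seq$residues) - 1L
  events <- as.integer(events)
  if (anyDuplicated(events)) stop("cleavage events must be distinct")
  if (is.unsorted(events)) stop("cleavage events must be sorted")
  if (any(events < first | events >= last))
    stop("cleavage event must lie within the substrate and not at its last residue")
  bounds <- c(first - 1L, events, last)
  roles <- if (length(events) == 0L) "intact"
           else if (length(events) == 1L) c("N-terminal", "C-terminal")
           else c("N-terminal", "released-tract", "C-terminal")
  frags <- do.call(rbind, lapply(seq_along(roles), function(i) {
    s <- bounds[i] + 1L
    e <- bounds[i + 1L]
    data.frame(start = s, end = e, length = e - s + 1L,
               mass_da = peptide_mass(.subseq(seq, s, e)),
               role = roles[i], stringsAsFactors = FALSE)
  }))
  class(frags) <- c("fragment_set", class(frags))
  attr(frags, "substrate") <- seq$identifier
  attr(frags, "events") <- events
  frags
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("Fragments of '", attr(x, "substrate"), "'", sep = "")
  ev <- attr(x, "events")
  if (length(ev)) cat(" after cleavage at", paste(ev, collapse = ", "))
  cat(" (masses are unmodified average masses; gel mobility will differ):\n")
  print.data.frame(data.frame(span = paste0(x$start, "-", x$end),
                              length = x$length,
                              mass_da = round(x$mass_da, 2), role = x$role),
                   row.names = FALSE)
  invisible(x)
}

#' Does a pair of cleavage events release the inhibitory tract?
#'
#' The tract spans `(proximal P1, distal P1]`: it is released when one event
#' cuts at or before the residue preceding the tract start and another cuts
#' at or after the tract end. A proximal cut falling strictly inside the
#' tract but at or before the first residue of the key inhibitory span
#' yields `"retained-partial"`: most of the key sequence still comes off,
#' clipped at its proximal end, which matches partial rather than full
#' activation. Any other configuration leaves the tract attached
#' (`"retained"`).
#'
#' @param events integer vector of P1 cleavage positions.
#' @param tract_span length-2 interval, author numbers, e.g. `c(139, 178)`.
#' @param key_span length-2 interval of the key inhibitory sequence within
#'   the tract, e.g. `c(153, 163)`.
#' @return list with `status` (`"released"`, `"retained-partial"`,
#'   `"retained"`) and `note`.
#' @export
tract_release_check <- function(events, tract_span, key_span = NULL) {
  stopifnot(length(tract_span) == 2L)
  events <- sort(as.integer(events))
  has_distal <- any(events >= tract_span[2])
  has_proximal <- any(events <= tract_span[1] - 1L)
  if (has_proximal && has_distal)
    return(list(status = "released", note = ""))
  inside <- events[events > tract_span[1] - 1L & events < tract_span[2]]
  if (has_distal && length(inside) > 0L && !is.null(key_span)) {
    prox <- min(inside)
    if (prox <= key_span[1]) {
      return(list(status = "retained-partial",
                  note = "key sequence truncated at proximal end"))
    }
    return(list(status = "retained-partial",
                note = "proximal cut inside key sequence"))
  }
  list(status = "retained", note = "tract not bracketed by cleavage events")
}

#' Write a fragment set as TSV
#' @param frags a `fragment_set`.
#' @param path output file.
#' @export
write_fragments_tsv <- function(frags, path) {
  out <- data.frame(span = paste0(frags$start, "-", frags$end),
                    length = frags$length, mass_da = frags$mass_da,
                    role = frags$role)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
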