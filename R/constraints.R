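# Flat-harmonic distance restraints and ambiguous (min-over-pairs)
# constraint scoring.

#' Flat-harmonic restraint penalty
#'
#' Zero inside the tolerance band `[x0 - tolerance, x0 + tolerance]`,
#' quadratic in the excursion beyond it, scaled by `sd`:
#' `((|d - x0| - tolerance)/sd)^2` outside the band. Continuous at both
#' band edges, and penalizes distances that are either too small or too
#' large.
#'
#' @param d Measured distance, Angstrom (vectorized).
#' @param x0 Restraint center, Angstrom.
#' @param sd Standard-deviation scale, Angstrom (> 0).
#' @param tolerance Flat half-width, Angstrom (>= 0).
#' @return Dimensionless penalty, same length as `d`.
#' @export
flat_harmonic <- function(d, x0, sd, tolerance) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (tolerance < 0) stop("tolerance must be >= 0")
  excess <- pmax(abs(d - x0) - tolerance, 0)
  (excess / sd)^2
}

#' Atom selector
#'
#' Identifies one atom in an assembly by chain, residue number and atom
#' name; printed/parsed as `chain:resno:atom`.
#'
#' @param chain Chain id.
#' @param resno Residue number.
#' @param atom Atom name (e.g. `"CA"`).
#' @return A list of class `atom_selector`.
#' @export
atom_selector <- function(chain, resno, atom) {
  structure(list(chain = as.character(chain), resno = as.integer(resno),
                 atom = as.character(atom)),
            class = "atom_selector")
}

format_selector <- function(s) sprintf("%s:%d:%s", s$chain, s$resno, s$atom)

parse_selector <- function(txt) {
  parts <- strsplit(txt, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 3L) stop("bad atom selector: ", txt)
  atom_selector(parts[1L], as.integer(parts[2L]), parts[3L])
}

#' Distance constraint between two atoms
#'
#' A flat-harmonic restraint between a pair of atom selectors. Defaults
#' follow the low-resolution assembly stage (x0 = 10 A, sd = 0.5,
#' tolerance = 5, on C-alpha atoms); the high-resolution stage uses
#' x0 = 4 A, sd = 2, tolerance = 0.5 on N-O salt-bridge pairs.
#'
#' @param sel_a,sel_b [atom_selector()] objects.
#' @param x0,sd,tolerance Flat-harmonic parameters (Angstrom).
#' @return An object of class `constraint_spec`.
#' @export
constraint_spec <- function(sel_a, sel_b, x0 = 10, sd = 0.5, tolerance = 5) {
  if (sd <= 0) stop("sd must be > 0")
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(list(sel_a = sel_a, sel_b = sel_b,
                 x0 = x0, sd = sd, tolerance = tolerance),
            class = "constraint_spec")
}

#' Ambiguous constraint: minimum over candidate pairs
#'
#' Scores as the minimum flat-harmonic penalty over its candidate
#' constraints (`min(C_1, ..., C_n)`), so only the best-satisfied pair
#' contributes. Used when the subunit arrangement is unknown and a
#' contact is known to exist between two subunits without knowing which
#' residue pair forms it.
#'
#' @param candidates Non-empty list of [constraint_spec()] objects.
#' @return An object of class `ambiguous_constraint`.
#' @export
ambiguous_constraint <- function(candidates) {
  if (length(candidates) < 1L) stop("ambiguous constraint needs >= 1 candidate")
  if (!all(vapply(candidates, inherits, logical(1L), "constraint_spec")))
    stop("candidates must be constraint_spec objects")
  structure(list(candidates = candidates), class = "ambiguous_constraint")
}

# Resolve a selector to coordinates inside an assembly.
resolve_selector <- function(assembly, sel) {
  for (s in assembly$subunits) {
    if (s$chain != sel$chain) next
    a <- s$atoms
    hit <- which(a$resno == sel$resno & a$name == sel$atom)
    if (length(hit) >= 1L)
      return(c(a$x[hit[1L]], a$y[hit[1L]], a$z[hit[1L]]))
    stop("unresolvable atom selector: ", format_selector(sel))
  }
  stop("unresolvable atom selector: ", format_selector(sel))
}

score_one <- function(assembly, cs) {
  pa <- resolve_selector(assembly, cs$sel_a)
  pb <- resolve_selector(assembly, cs$sel_b)
  d <- sqrt(sum((pa - pb)^2))
  list(distance = d,
       penalty = flat_harmonic(d, cs$x0, cs$sd, cs$tolerance))
}

#' Score an assembly against a set of distance constraints
#'
#' Plain constraints contribute their flat-harmonic penalty; ambiguous
#' constraints contribute the minimum penalty over their candidates.
#' The total is the sum.
#'
#' @param assembly A `pilus_assembly`.
#' @param constraints List of `constraint_spec` / `ambiguous_constraint`
#'   objects.
#' @return List with `total` and a data frame `breakdown` (one row per
#'   constraint: type, selected pair, distance, penalty).
#' @export
score_constraints <- function(assembly, constraints) {
  rows <- lapply(seq_along(constraints), function(i) {
    con <- constraints[[i]]
    if (inherits(con, "constraint_spec")) {
      s <- score_one(assembly, con)
      data.frame(index = i, type = "plain",
                 pair = paste(format_selector(con$sel_a),
                              format_selector(con$sel_b)),
                 distance = s$distance, penalty = s$penalty,
                 stringsAsFactors = FALSE)
    } else if (inherits(con, "ambiguous_constraint")) {
      scored <- lapply(con$candidates, function(cc) score_one(assembly, cc))
      pens <- vapply(scored, `[[`, numeric(1L), "penalty")
      best <- which.min(pens)
      bc <- con$candidates[[best]]
      data.frame(index = i, type = "ambiguous",
                 pair = paste(format_selector(bc$sel_a),
                              format_selector(bc$sel_b)),
                 distance = scored[[best]]$distance, penalty = pens[best],
                 stringsAsFactors = FALSE)
    } else stop("unknown constraint object at position ", i)
  })
  breakdown <- do.call(rbind, rows)
  list(total = sum(breakdown$penalty), breakdown = breakdown)
}

#' Default ambiguous contacts between the middle subunit and those above
#'
#' By symmetry only one subunit's contacts need restraining: the middle
#' chain (index `floor(n/2)`, 0-based from the bottom) is linked to each
#' of the `n_upper` chains above it by one ambiguous constraint whose
#' candidates enumerate all combinations of the supplied residue pairs.
#'
#' @param assembly A `pilus_assembly`.
#' @param residues_mid,residues_other Residue numbers eligible on the
#'   middle and the partner chain.
#' @param atom Atom name used for the distance (default `"CA"`).
#' @param x0,sd,tolerance Flat-harmonic parameters (low-resolution
#'   defaults).
#' @param n_upper Number of chains above the middle to link (default 10).
#' @return List of `ambiguous_constraint` objects.
#' @export
middle_upper_contacts <- function(assembly, residues_mid, residues_other,
                                  atom = "CA", x0 = 10, sd = 0.5,
                                  tolerance = 5, n_upper = 10L) {
  n <- length(assembly$subunits)
  mid <- n %/% 2L + 1L                     # 1-based index of chain floor(n/2)
  upper <- seq.int(mid + 1L, min(n, mid + n_upper))
  chains <- vapply(assembly$subunits, `[[`, character(1L), "chain")
  lapply(upper, function(j) {
    cands <- list()
    for (ra in residues_mid) for (rb in residues_other) {
      cands[[length(cands) + 1L]] <- constraint_spec(
        atom_selector(chains[mid], ra, atom),
        atom_selector(chains[j], rb, atom),
        x0 = x0, sd = sd, tolerance = tolerance)
    }
    ambiguous_constraint(cands)
  })
}

# ---------------------------------------------------------------------------
# Constraint file round-trip
# Format: one restraint per line --
#   PAIR chain:res:atom chain:res:atom x0 sd tol
# ambiguous blocks: an AMBIG header followed by indented PAIR lines.

#' Write constraints to a restraint file
#'
#' @param constraints List of constraint objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_constraints <- function(constraints, path) {
  fmt <- function(cs, indent = "")
    sprintf("%sPAIR %s %s %g %g %g", indent,
            format_selector(cs$sel_a), format_selector(cs$sel_b),
            cs$x0, cs$sd, cs$tolerance)
  lines <- unlist(lapply(constraints, function(con) {
    if (inherits(con, "constraint_spec")) fmt(con)
    else c("AMBIG", vapply(con$candidates, fmt, character(1L),
                           indent = "  "))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read constraints from a restraint file
#'
#' @param path Path written by [write_constraints()].
#' @return List of `constraint_spec` / `ambiguous_constraint` objects.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parse_pair <- function(ln) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(tok) != 6L || tok[1L] != "PAIR")
      stop("bad restraint line: ", ln)
    constraint_spec(parse_selector(tok[2L]), parse_selector(tok[3L]),
                    x0 = as.numeric(tok[4L]), sd = as.numeric(tok[5L]),
                    tolerance = as.numeric(tok[6L]))
  }
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (trimws(ln) == "AMBIG") {
      cands <- list()
      i <- i + 1L
      while (i <= length(lines) && grepl("^\\s+PAIR", lines[[i]])) {
        cands[[length(cands) + 1L]] <- parse_pair(lines[[i]])
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- ambiguous_constraint(cands)
    } else {
      out[[length(out) + 1L]] <- parse_pair(ln)
      i <- i + 1L
    }
  }
  out
}
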