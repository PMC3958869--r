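# Hydrogen-suppressed molecular graphs from a SMILES subset.
#
# The supported dialect is deliberately narrow: atoms C/N/O/F/Cl/Br/I,
# aromatic c/n/o, branches, single-digit ring closures, and explicit -/=/#
# bonds. Charges, isotopes, stereo markers, bracket atoms and dot-separated
# fragments are rejected loudly rather than mis-parsed.

.ELEMENTS <- data.frame(
  element = c("C", "N", "O", "F", "Cl", "Br", "I"),
  z       = c(6L, 7L, 8L, 9L, 17L, 35L, 53L),
  zv      = c(4L, 5L, 6L, 7L, 7L, 7L, 7L),
  std_valence = c(4L, 3L, 2L, 1L, 1L, 1L, 1L),
  weight  = c(12.011, 14.007, 15.999, 18.998, 35.45, 79.904, 126.904),
  stringsAsFactors = FALSE
)

#' Parse a SMILES string into a molecular graph
#'
#' Builds a hydrogen-suppressed molecular graph: heavy atoms as nodes with
#' implicit-hydrogen counts, bonds with explicit Kekule orders, and ring
#' perception. Lowercase-aromatic input is Kekulized immediately so that all
#' downstream descriptor code sees alternating single/double bonds; for
#' benzenoid systems every valid Kekule assignment yields identical
#' descriptor values, and the assignment chosen is the first found by
#' depth-first matching from the lowest atom index.
#'
#' Supported tokens: `C N O F Cl Br I`, aromatic `c n o`, branches `( )`,
#' ring-closure digits `0`-`9`, and bond symbols `-`, `=`, `#`. Anything
#' else (brackets, charges, stereo, isotopes, `.`) is a parse error naming
#' the offending token and its position.
#'
#' @param smiles SMILES string in the supported subset.
#' @param name Optional compound label carried on the result.
#' @return An object of class `molecule`: a list with components
#'   `atoms` (data.frame: `element`, `aromatic`, `implicit_h`,
#'   `valence_electrons`, `atomic_number`, `degree`),
#'   `bonds` (data.frame: `i`, `j`, `order`, `aromatic`, `in_ring`),
#'   `ring_count`, `aromatic_ring_count`, `name`, `smiles`.
#' @examples
#' parse_smiles("c1ccccc1", "benzene")
#' parse_smiles("CC(C)C#N")
#' @export
parse_smiles <- function(smiles, name = NULL) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("`smiles` must be a single non-empty string", call. = FALSE)
  }

  chars <- strsplit(smiles, "")[[1]]
  n_char <- length(chars)

  element <- character(0)
  aromatic <- logical(0)
  bond_i <- integer(0); bond_j <- integer(0)
  bond_order <- integer(0); bond_arom <- logical(0)

  prev <- NA_integer_          # atom the next bond attaches to
  stack <- integer(0)          # saved attachment points for branches
  pending <- NA_integer_       # explicit bond order waiting for next atom
  ring_open <- list()          # digit -> list(atom, order)
  ring_pairs <- 0L

  err <- function(tok, pos, why) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s", pos, tok, why),
         call. = FALSE)
  }

  add_bond <- function(a, b, order, arom) {
    if (a == b) err(smiles, 0L, "bond joins an atom to itself")
    dup <- any((bond_i == a & bond_j == b) | (bond_i == b & bond_j == a))
    if (dup) stop(sprintf("duplicate bond between atoms %d and %d", a, b),
                  call. = FALSE)
    bond_i <<- c(bond_i, a); bond_j <<- c(bond_j, b)
    bond_order <<- c(bond_order, order); bond_arom <<- c(bond_arom, arom)
  }

  add_atom <- function(el, arom) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    idx <- length(element)
    if (!is.na(prev)) {
      both_arom <- arom && aromatic[prev]
      if (is.na(pending)) {
        add_bond(prev, idx, 1L, both_arom)
      } else {
        add_bond(prev, idx, pending, FALSE)
      }
    } else if (idx > 1L) {
      stop("disconnected SMILES (multiple fragments) are not supported",
           call. = FALSE)
    }
    prev <<- idx
    pending <<- NA_integer_
  }

  i <- 1L
  while (i <= n_char) {
    ch <- chars[i]
    two <- if (i < n_char) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      add_atom(two, FALSE); i <- i + 2L; next
    }
    if (ch %in% c("C", "N", "O", "F", "I")) {
      add_atom(ch, FALSE)
    } else if (ch %in% c("c", "n", "o")) {
      add_atom(toupper(ch), TRUE)
    } else if (ch %in% as.character(0:9)) {
      if (is.na(prev)) err(ch, i, "ring closure before any atom")
      key <- ch
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev, order = pending)
      } else {
        opened <- ring_open[[key]]
        order <- if (!is.na(pending)) pending
                 else if (!is.na(opened$order)) opened$order
                 else NA_integer_
        both_arom <- aromatic[opened$atom] && aromatic[prev]
        if (is.na(order)) {
          add_bond(opened$atom, prev, 1L, both_arom)
        } else {
          add_bond(opened$atom, prev, order, FALSE)
        }
        ring_open[[key]] <- NULL
        ring_pairs <- ring_pairs + 1L
      }
      pending <- NA_integer_
    } else if (ch == "(") {
      if (is.na(prev)) err(ch, i, "branch before any atom")
      stack <- c(stack, prev)
    } else if (ch == ")") {
      if (length(stack) == 0L) err(ch, i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (ch == "-") {
      pending <- 1L
    } else if (ch == "=") {
      pending <- 2L
    } else if (ch == "#") {
      pending <- 3L
    } else {
      err(ch, i, "unsupported token (subset: C N O F Cl Br I c n o ( ) - = # digits)")
    }
    i <- i + 1L
  }

  if (length(stack) > 0L) stop("unclosed branch '(' in SMILES", call. = FALSE)
  if (length(ring_open) > 0L) {
    stop(sprintf("unclosed ring bond(s): digit %s",
                 paste(names(ring_open), collapse = ", ")), call. = FALSE)
  }
  n_atoms <- length(element)
  if (n_atoms == 0L) stop("SMILES contains no atoms", call. = FALSE)

  # connectivity (single component); the parser can only produce a
  # disconnected graph via unreachable code paths, but check anyway
  if (n_atoms > 1L) {
    comp <- .components(n_atoms, bond_i, bond_j)
    if (max(comp) > 1L) {
      stop("molecular graph is disconnected", call. = FALSE)
    }
  }

  # Kekulize aromatic bonds
  korder <- .kekulize(element, aromatic, bond_i, bond_j, bond_order, bond_arom)

  info <- .ELEMENTS[match(element, .ELEMENTS$element), ]
  bond_sum <- rep(0L, n_atoms)
  if (length(bond_i)) {
    for (q in seq_along(bond_i)) {
      bond_sum[bond_i[q]] <- bond_sum[bond_i[q]] + korder[q]
      bond_sum[bond_j[q]] <- bond_sum[bond_j[q]] + korder[q]
    }
  }
  implicit_h <- info$std_valence - bond_sum
  if (any(implicit_h < 0L)) {
    bad <- which(implicit_h < 0L)[1]
    stop(sprintf("valence violation at atom %d (%s): bond orders sum to %d, standard valence %d",
                 bad, element[bad], bond_sum[bad], info$std_valence[bad]),
         call. = FALSE)
  }

  degree <- rep(0L, n_atoms)
  if (length(bond_i)) {
    tab <- table(factor(c(bond_i, bond_j), levels = seq_len(n_atoms)))
    degree <- as.integer(tab)
  }

  ring_count <- length(bond_i) - n_atoms + 1L
  in_ring <- .ring_bonds(n_atoms, bond_i, bond_j)
  aromatic_ring_count <- .aromatic_ring_count(n_atoms, bond_i, bond_j, bond_arom)

  atoms <- data.frame(
    element = element,
    aromatic = aromatic,
    implicit_h = as.integer(implicit_h),
    valence_electrons = info$zv,
    atomic_number = info$z,
    degree = degree,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    i = bond_i, j = bond_j,
    order = korder,
    aromatic = bond_arom,
    in_ring = in_ring
  )

  structure(
    list(atoms = atoms, bonds = bonds,
         ring_count = ring_count,
         aromatic_ring_count = aromatic_ring_count,
         ring_closure_pairs = ring_pairs,
         name = if (is.null(name)) NA_character_ else as.character(name),
         smiles = smiles),
    class = "molecule"
  )
}

# connected-component labels by BFS
.components <- function(n, bi, bj, skip = 0L) {
  adj <- vector("list", n)
  for (q in seq_along(bi)) {
    if (q == skip) next
    adj[[bi[q]]] <- c(adj[[bi[q]]], bj[q])
    adj[[bj[q]]] <- c(adj[[bj[q]]], bi[q])
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# a bond is in a ring iff removing it leaves its endpoints connected
.ring_bonds <- function(n, bi, bj) {
  if (!length(bi)) return(logical(0))
  vapply(seq_along(bi), function(q) {
    comp <- .components(n, bi, bj, skip = q)
    comp[bi[q]] == comp[bj[q]]
  }, logical(1))
}

# cyclomatic number of the subgraph of aromatic-origin bonds, summed over its
# connected components: the number of aromatic rings (2 for naphthalene and
# for biphenyl, 1 per isolated benzene ring)
.aromatic_ring_count <- function(n, bi, bj, arom) {
  keep <- which(arom)
  if (!length(keep)) return(0L)
  verts <- sort(unique(c(bi[keep], bj[keep])))
  remap <- match(seq_len(n), verts)
  comp <- .components(length(verts), remap[bi[keep]], remap[bj[keep]])
  length(keep) - length(verts) + max(comp)
}

# Deterministic Kekulization: a matching over aromatic-origin bonds in which
# every aromatic carbon is covered (aromatic N/O may stay uncovered: pyridine
# N gets matched if needed, furan O never requires a double bond). Matched
# bonds become double, remaining aromatic bonds single. Depth-first with
# backtracking from the lowest atom index.
.kekulize <- function(element, aromatic, bi, bj, order, arom_bond) {
  korder <- order
  if (!any(arom_bond)) return(korder)

  arom_atoms <- which(aromatic)
  must_match <- aromatic & element == "C"
  adj <- lapply(seq_along(aromatic), function(a) {
    qs <- which(arom_bond & (bi == a | bj == a))
    other <- ifelse(bi[qs] == a, bj[qs], bi[qs])
    ord <- order(other)
    list(q = qs[ord], other = other[ord])
  })

  matched <- rep(NA_integer_, length(aromatic))  # partner bond index
  try_atom <- function(atoms_left) {
    if (!length(atoms_left)) return(TRUE)
    a <- atoms_left[1]
    rest <- atoms_left[-1]
    if (!is.na(matched[a]) || !must_match[a]) return(try_atom(rest))
    nb <- adj[[a]]
    for (t in seq_along(nb$q)) {
      b <- nb$other[t]
      if (!is.na(matched[b])) next
      q <- nb$q[t]
      matched[a] <<- q; matched[b] <<- q
      if (try_atom(rest)) return(TRUE)
      matched[a] <<- NA_integer_; matched[b] <<- NA_integer_
    }
    FALSE
  }
  ok <- try_atom(sort(arom_atoms))
  if (!ok) {
    stop("Kekulization failed: no alternating single/double assignment covers every aromatic carbon",
         call. = FALSE)
  }
  dbl <- unique(matched[!is.na(matched)])
  korder[dbl] <- 2L
  korder
}

#' Molecular formula in Hill order
#'
#' Carbon first, then hydrogen (implicit counts), then remaining elements
#' alphabetically.
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @return A formula string such as `"C7H8"`.
#' @examples
#' hill_formula(parse_smiles("Cc1ccccc1")) # "C7H8"
#' @export
hill_formula <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  counts <- table(mol$atoms$element)
  n_h <- sum(mol$atoms$implicit_h)
  part <- function(el, n) {
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }
  out <- part("C", if ("C" %in% names(counts)) counts[["C"]] else 0L)
  out <- paste0(out, part("H", n_h))
  rest <- sort(setdiff(names(counts), "C"))
  for (el in rest) out <- paste0(out, part(el, counts[[el]]))
  out
}

#' Molecular weight from standard atomic weights
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @return Molecular weight in g/mol, including implicit hydrogens.
#' @export
molecular_weight <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  w <- .ELEMENTS$weight[match(mol$atoms$element, .ELEMENTS$element)]
  sum(w) + sum(mol$atoms$implicit_h) * 1.008
}

#' @export
print.molecule <- function(x, ...) {
  nm <- if (is.na(x$name)) "" else paste0(" (", x$name, ")")
  cat(sprintf("<molecule%s> %s\n", nm, x$smiles))
  cat(sprintf("  formula %s, %d heavy atoms, %d bonds, %d ring(s) of which %d aromatic\n",
              hill_formula(x), nrow(x$atoms), nrow(x$bonds),
              x$ring_count, x$aromatic_ring_count))
  invisible(x)
}
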