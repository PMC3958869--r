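# Molecular descriptors for the PDMS-water QSPR: additive polarizability,
# first-order valence connectivity index, and the hydrogen-bonding indicator.

#' Group-contribution polarizability scheme
#'
#' The default contribution factors of the additive polarizability
#' descriptor, one per atom/bond feature, plus the counting conventions the
#' descriptor engine uses. The defaults reproduce the published training and
#' test tables (see `vignette("spme-kfw-methods")` for the back-calculated
#' conventions):
#'
#' * an aromatic ring contributes three double-bond terms and no cycle term
#'   (fused systems contribute three per ring: naphthalene counts six);
#' * all hydrogens are counted, including those on O and N
#'   (`count_heteroatom_hydrogens = FALSE` restores the literal
#'   attached-to-carbon-only footnote convention);
#' * nitrogen carries an explicit factor of 0;
#' * every oxygen takes the plain oxygen factor; the separate hydroxyl
#'   factor is applied only when `hydroxyl_factor = "aliphatic"`, to -OH
#'   groups on saturated non-aromatic carbons.
#'
#' @param factors Named numeric vector overriding individual contribution
#'   factors. Known features: `carbon`, `hydrogen`, `nitrogen`, `oxygen`,
#'   `hydroxyl`, `chlorine`, `bromine`, `iodine`, `fluorine`, `cycle`,
#'   `double_bond`, `triple_bond`.
#' @param count_heteroatom_hydrogens Count hydrogens on N/O (default) or
#'   only those attached to carbon.
#' @param aromatic_ring_counts_cycle Should aromatic rings also contribute
#'   the cycle term? Default `FALSE` (forced by back-calculation of the
#'   published aromatic values).
#' @param hydroxyl_factor `"none"` (default: all oxygens take the oxygen
#'   factor) or `"aliphatic"` (apply the hydroxyl factor to sp3 C-OH).
#' @return A list of class `polarizability_scheme`.
#' @examples
#' pdms_scheme()
#' pdms_scheme(factors = c(carbon = 0.6))
#' @export
pdms_scheme <- function(factors = NULL,
                        count_heteroatom_hydrogens = TRUE,
                        aromatic_ring_counts_cycle = FALSE,
                        hydroxyl_factor = c("none", "aliphatic")) {
  hydroxyl_factor <- match.arg(hydroxyl_factor)
  f <- c(
    carbon      =  0.577,
    hydrogen    = -0.120,
    nitrogen    =  0.000,
    oxygen      = -0.825,
    hydroxyl    = -3.701,
    chlorine    = -0.187,
    bromine     = -0.222,
    iodine      =  0.407,
    fluorine    = -0.570,
    cycle       = -0.952,
    double_bond = -0.859,
    triple_bond = -0.109
  )
  if (!is.null(factors)) {
    if (is.null(names(factors)) || !all(nzchar(names(factors)))) {
      stop("`factors` must be a named numeric vector", call. = FALSE)
    }
    unknown <- setdiff(names(factors), names(f))
    if (length(unknown)) {
      stop("unknown polarizability feature(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    f[names(factors)] <- factors
  }
  structure(
    list(factors = f,
         count_heteroatom_hydrogens = count_heteroatom_hydrogens,
         aromatic_ring_counts_cycle = aromatic_ring_counts_cycle,
         hydroxyl_factor = hydroxyl_factor),
    class = "polarizability_scheme"
  )
}

#' Read a polarizability scheme override from a JSON file
#'
#' The file holds a single JSON object mapping feature names to contribution
#' factors, e.g. `{"carbon": 0.6, "cycle": -1.0}`; unknown feature names are
#' an error.
#'
#' @param path JSON file path.
#' @param ... Passed to [pdms_scheme()] (counting-convention flags).
#' @return A `polarizability_scheme`.
#' @export
read_scheme <- function(path, ...) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pdms_scheme(factors = unlist(raw), ...)
}

#' Valence delta values of every atom
#'
#' For each heavy atom the delta value is the difference between its valence
#' electron count and the number of attached hydrogens. For third-row and
#' heavier halogens (Cl, Br, I) that definition fails to reproduce the
#' published connectivity indices and the Kier-Hall higher-row form is used
#' instead: `(Zv - h) / (Z - Zv - 1)`. Bond orders never enter: a carbonyl
#' carbon and a methine carbon with equal hydrogen counts share a delta.
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @return Numeric vector of delta values, one per atom.
#' @examples
#' valence_delta(parse_smiles("c1ccccc1")) # all 3
#' @export
valence_delta <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms
  delta <- ifelse(
    a$atomic_number <= 9L,
    a$valence_electrons - a$implicit_h,
    (a$valence_electrons - a$implicit_h) /
      (a$atomic_number - a$valence_electrons - 1L)
  )
  if (any(delta <= 0)) {
    bad <- which(delta <= 0)[1]
    stop(sprintf("non-positive delta value at atom %d (%s)", bad,
                 a$element[bad]), call. = FALSE)
  }
  delta
}

#' First-order valence molecular connectivity index
#'
#' Sum over all bonds of `(delta_i * delta_j)^-0.5`, each bond counted once
#' regardless of its order. A molecule with no bonds (methane) scores 0.
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @return The connectivity index (dimensionless).
#' @examples
#' chi1(parse_smiles("c1ccccc1"))  # 2.000
#' chi1(parse_smiles("CC"))        # 1.000
#' @export
chi1 <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (nrow(mol$bonds) == 0L) return(0)
  d <- valence_delta(mol)
  sum((d[mol$bonds$i] * d[mol$bonds$j])^-0.5)
}

#' Tally the atom/bond features of the polarizability scheme
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @param scheme A [pdms_scheme()]; its flags control hydrogen counting,
#'   the aromatic cycle convention and hydroxyl classification.
#' @return Named integer vector over the scheme's feature vocabulary.
#' @examples
#' count_features(parse_smiles("C1CCCC1"))  # 5 C, 10 H, 1 cycle
#' @export
count_features <- function(mol, scheme = pdms_scheme()) {
  stopifnot(inherits(mol, "molecule"), inherits(scheme, "polarizability_scheme"))
  a <- mol$atoms; b <- mol$bonds
  n <- stats::setNames(integer(length(scheme$factors)), names(scheme$factors))

  n[["carbon"]]   <- sum(a$element == "C")
  n[["nitrogen"]] <- sum(a$element == "N")
  n[["chlorine"]] <- sum(a$element == "Cl")
  n[["bromine"]]  <- sum(a$element == "Br")
  n[["iodine"]]   <- sum(a$element == "I")
  n[["fluorine"]] <- sum(a$element == "F")

  if (scheme$count_heteroatom_hydrogens) {
    n[["hydrogen"]] <- sum(a$implicit_h)
  } else {
    n[["hydrogen"]] <- sum(a$implicit_h[a$element == "C"])
  }

  # oxygen classification
  ox <- which(a$element == "O")
  n_hydroxyl <- 0L
  if (length(ox) && scheme$hydroxyl_factor == "aliphatic") {
    for (o in ox) {
      nb_bonds <- b$i == o | b$j == o
      if (sum(nb_bonds) != 1L || a$implicit_h[o] != 1L) next
      nb <- setdiff(c(b$i[nb_bonds], b$j[nb_bonds]), o)
      sp3_c <- a$element[nb] == "C" && !a$aromatic[nb] &&
        all(b$order[b$i == nb | b$j == nb] == 1L)
      if (sp3_c) n_hydroxyl <- n_hydroxyl + 1L
    }
  }
  n[["hydroxyl"]] <- n_hydroxyl
  n[["oxygen"]] <- length(ox) - n_hydroxyl

  # unsaturation: each aromatic ring contributes three double-bond terms;
  # explicit (non-aromatic-origin) multiple bonds count individually
  explicit_double <- sum(b$order == 2L & !b$aromatic)
  n[["double_bond"]] <- 3L * mol$aromatic_ring_count + explicit_double
  n[["triple_bond"]] <- sum(b$order == 3L)

  n_cycle <- mol$ring_count - mol$aromatic_ring_count
  if (scheme$aromatic_ring_counts_cycle) n_cycle <- mol$ring_count
  n[["cycle"]] <- n_cycle

  n
}

#' Additive polarizability descriptor
#'
#' Dot product of the molecule's feature tallies with the scheme's
#' contribution factors.
#'
#' @inheritParams count_features
#' @return The polarizability descriptor (dimensionless).
#' @examples
#' polarizability(parse_smiles("C1CCCC1"))  # 0.733
#' @export
polarizability <- function(mol, scheme = pdms_scheme()) {
  counts <- count_features(mol, scheme)
  missing <- names(counts)[counts > 0L & is.na(scheme$factors[names(counts)])]
  if (length(missing)) {
    stop("no contribution factor for feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(counts * scheme$factors[names(counts)])
}

#' Hydrogen-bonding indicator variable
#'
#' Returns 1 when the compound can take part in hydrogen bonding under the
#' structural rules used for the partition model:
#' (a) an electronegative element (N, O or halogen) bonded directly to a
#' carbon that itself carries at least one hydrogen; (b) a carbon-carbon
#' triple bond (acetylenic compounds); or (c) an aromatic ring carbon
#' carrying a hydrogen (partially substituted aromatics). Otherwise 0.
#'
#' @param mol A [parse_smiles()] `molecule`.
#' @return Integer 0 or 1.
#' @examples
#' hb_indicator(parse_smiles("C1CCCCC1"))  # 0
#' hb_indicator(parse_smiles("Cc1ccccc1")) # 1
#' @export
hb_indicator <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  a <- mol$atoms; b <- mol$bonds
  electroneg <- c("N", "O", "F", "Cl", "Br", "I")

  if (nrow(b)) {
    for (q in seq_len(nrow(b))) {
      pair <- c(b$i[q], b$j[q])
      for (k in 1:2) {
        en <- pair[k]; other <- pair[3 - k]
        if (a$element[en] %in% electroneg &&
            a$element[other] == "C" && a$implicit_h[other] >= 1L) {
          return(1L)
        }
      }
    }
    cc_triple <- b$order == 3L &
      a$element[b$i] == "C" & a$element[b$j] == "C"
    if (any(cc_triple)) return(1L)
  }
  if (any(a$aromatic & a$element == "C" & a$implicit_h >= 1L)) return(1L)
  0L
}

#' Compute the full descriptor set of a molecule
#'
#' Assembles the three structure-derived descriptors (connectivity index,
#' polarizability, indicator) together with the molecular weight and any
#' measured extras supplied by the caller.
#'
#' @inheritParams count_features
#' @param ws Optional water solubility (mg/L), passed through.
#' @param log_kow Optional log10 octanol-water partition coefficient,
#'   passed through.
#' @return A one-row data.frame with columns `name`, `smiles`, `chi1`,
#'   `phi`, `indicator`, `mw`, `ws`, `log_kow`.
#' @examples
#' compute_descriptors(parse_smiles("c1ccccc1", "benzene"))
#' @export
compute_descriptors <- function(mol, scheme = pdms_scheme(),
                                ws = NA_real_, log_kow = NA_real_) {
  stopifnot(inherits(mol, "molecule"))
  data.frame(
    name = mol$name,
    smiles = mol$smiles,
    chi1 = chi1(mol),
    phi = polarizability(mol, scheme),
    indicator = hb_indicator(mol),
    mw = molecular_weight(mol),
    ws = as.numeric(ws),
    log_kow = as.numeric(log_kow),
    stringsAsFactors = FALSE
  )
}

#' Batch descriptor computation over SMILES strings
#'
#' @param smiles Character vector of SMILES.
#' @param names Optional labels (recycled from `smiles` when absent).
#' @param scheme A [pdms_scheme()].
#' @param .error How to treat per-molecule failures: `"stop"` (default) or
#'   `"report"`, which leaves the failed row's descriptors `NA` and fills an
#'   `error` column.
#' @return A data.frame, one row per input, with descriptor columns and
#'   (for `.error = "report"`) an `error` column.
#' @export
descriptor_table <- function(smiles, names = NULL, scheme = pdms_scheme(),
                             .error = c("stop", "report")) {
  .error <- match.arg(.error)
  if (is.null(names)) names <- smiles
  stopifnot(length(names) == length(smiles))
  rows <- lapply(seq_along(smiles), function(k) {
    res <- tryCatch(
      cbind(compute_descriptors(parse_smiles(smiles[k], names[k]), scheme),
            error = NA_character_, stringsAsFactors = FALSE),
      error = function(e) {
        if (.error == "stop") stop(e)
        data.frame(name = names[k], smiles = smiles[k], chi1 = NA_real_,
                   phi = NA_real_, indicator = NA_integer_, mw = NA_real_,
                   ws = NA_real_, log_kow = NA_real_,
                   error = conditionMessage(e), stringsAsFactors = FALSE)
      }
    )
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
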