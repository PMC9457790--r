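# ---- exact rational coefficients ------------------------------------------
# Stoichiometric coefficients are carried as reduced integer pairs (num, den)
# so every conversion ratio the partition estimator consumes is exact; no
# floating-point rounding can leak into the mass balance.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

.rat <- function(num, den = 1L) {
  num <- as.integer(num); den <- as.integer(den)
  if (is.na(num) || is.na(den) || den == 0L)
    stop("invalid rational coefficient", call. = FALSE)
  if (den < 0L) { num <- -num; den <- -den }
  g <- .gcd(num, den)
  if (g > 1L) { num <- num %/% g; den <- den %/% g }
  c(num = num, den = den)
}

# parse 3, "3" or "3/2" into a reduced rational pair
.parse_coef <- function(x) {
  if (is.numeric(x)) {
    if (x %% 1 == 0) return(.rat(x))
    # tolerate simple non-integers (halves, quarters) from config files
    for (d in 2:64) if (abs(x * d - round(x * d)) < 1e-9) return(.rat(round(x * d), d))
    stop("coefficient ", x, " is not a simple rational", call. = FALSE)
  }
  x <- trimws(as.character(x))
  if (grepl("/", x, fixed = TRUE)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
    return(.rat(as.integer(parts[1L]), as.integer(parts[2L])))
  }
  .rat(as.integer(x))
}

.rat_value <- function(r) r[["num"]] / r[["den"]]

# a/b for two rational pairs, exact
.rat_div <- function(a, b) .rat(a[["num"]] * b[["den"]], a[["den"]] * b[["num"]])

# ---- species registry ------------------------------------------------------

#' Chemical species of the NRFO reaction network
#'
#' Returns the registry of predefined species used by the stoichiometry
#' checker: elemental composition, formal charge and, where the element is
#' redox-active in this network, the per-atom oxidation state of N or Fe.
#' The canonical network tracks dissolved \eqn{Fe^{3+}}; the mineral
#' FeO(OH) is registered only so that literature variants of the
#' chemodenitrification equation written with an oxyhydroxide product can
#' be encoded and balance-checked.
#'
#' @return A named list; each entry has `elements` (named integer vector),
#'   `charge` (integer), and optional `n_ox` / `fe_ox` per-atom oxidation
#'   states.
#' @examples
#' nrfo_species()[["NO3-"]]
#' @export
nrfo_species <- function() {
  list(
    "NO3-"    = list(elements = c(N = 1L, O = 3L), charge = -1L, n_ox = 5L),
    "NO2-"    = list(elements = c(N = 1L, O = 2L), charge = -1L, n_ox = 3L),
    "N2O"     = list(elements = c(N = 2L, O = 1L), charge =  0L, n_ox = 1L),
    "N2"      = list(elements = c(N = 2L),         charge =  0L, n_ox = 0L),
    "Fe2+"    = list(elements = c(Fe = 1L),        charge =  2L, fe_ox = 2L),
    "Fe3+"    = list(elements = c(Fe = 1L),        charge =  3L, fe_ox = 3L),
    "H+"      = list(elements = c(H = 1L),         charge =  1L),
    "H2O"     = list(elements = c(H = 2L, O = 1L), charge =  0L),
    # auxiliary mineral species, not part of the canonical network
    "FeO(OH)" = list(elements = c(Fe = 1L, O = 2L, H = 1L), charge = 0L,
                     fe_ox = 3L)
  )
}

# ---- reactions -------------------------------------------------------------

.coef_table <- function(x, side) {
  if (length(x) == 0L) stop("empty ", side, " side", call. = FALSE)
  nms <- names(x)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("all ", side, " coefficients must be named by species", call. = FALSE)
  reg <- nrfo_species()
  unknown <- setdiff(nms, names(reg))
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "), call. = FALSE)
  coefs <- lapply(x, .parse_coef)
  for (i in seq_along(coefs))
    if (coefs[[i]][["num"]] <= 0L)
      stop("coefficient of ", nms[i], " must be > 0", call. = FALSE)
  names(coefs) <- nms
  coefs
}

#' Construct a stoichiometric reaction
#'
#' Coefficients may be integers, or rationals written `"p/q"`; they are
#' stored exactly. Species must come from [nrfo_species()].
#'
#' @param label Short text label.
#' @param reactants,products Named vectors/lists mapping species to positive
#'   coefficients, e.g. `c("NO3-" = 1, "Fe2+" = 2, "H+" = 2)`.
#' @return An object of class `nrfo_reaction`.
#' @examples
#' r <- reaction("eq1", c("NO3-" = 1, "Fe2+" = 2, "H+" = 2),
#'               c("Fe3+" = 2, "NO2-" = 1, "H2O" = 1))
#' check_balance(r)
#' @export
reaction <- function(label, reactants, products) {
  lhs <- .coef_table(reactants, "reactant")
  rhs <- .coef_table(products, "product")
  both <- intersect(names(lhs), names(rhs))
  if (length(both))
    stop("species on both sides: ", paste(both, collapse = ", "), call. = FALSE)
  structure(list(label = label, reactants = lhs, products = rhs),
            class = "nrfo_reaction")
}

#' @export
print.nrfo_reaction <- function(x, ...) {
  fmt <- function(side) paste(vapply(names(side), function(s) {
    r <- side[[s]]
    co <- if (r[["den"]] == 1L) {
      if (r[["num"]] == 1L) "" else paste0(r[["num"]], " ")
    } else paste0(r[["num"]], "/", r[["den"]], " ")
    paste0(co, s)
  }, character(1)), collapse = " + ")
  cat(sprintf("<%s> %s -> %s\n", x$label, fmt(x$reactants), fmt(x$products)))
  invisible(x)
}

#' The canonical NRFO reaction pair
#'
#' `enzymatic`: microbial nitrate reduction to nitrite with Fe(II) as the
#' electron donor (2 Fe(II) per nitrate). `chemodenitrification`: abiotic
#' nitrite reduction by Fe(II) to N2O (4 Fe(II) per 2 nitrite per N2O).
#'
#' @return A named list of two `nrfo_reaction` objects.
#' @examples
#' nrfo_reactions()$enzymatic
#' @export
nrfo_reactions <- function() {
  list(
    enzymatic = reaction(
      "enzymatic NRFO",
      c("NO3-" = 1, "Fe2+" = 2, "H+" = 2),
      c("Fe3+" = 2, "NO2-" = 1, "H2O" = 1)
    ),
    chemodenitrification = reaction(
      "chemodenitrification",
      c("NO2-" = 2, "Fe2+" = 4, "H+" = 6),
      c("N2O" = 1, "Fe3+" = 4, "H2O" = 3)
    )
  )
}

# ---- balance checking ------------------------------------------------------

.side_sums <- function(side) {
  reg <- nrfo_species()
  elements <- numeric(0)
  charge <- 0
  n_ox_sum <- 0   # sum over coef * atoms * per-atom oxidation state
  fe_ox_sum <- 0
  for (s in names(side)) {
    co <- .rat_value(side[[s]])
    info <- reg[[s]]
    for (el in names(info$elements)) {
      elements[el] <- (if (is.na(elements[el])) 0 else elements[el]) +
        co * info$elements[[el]]
    }
    charge <- charge + co * info$charge
    if (!is.null(info$n_ox))  n_ox_sum  <- n_ox_sum  + co * info$elements[["N"]]  * info$n_ox
    if (!is.null(info$fe_ox)) fe_ox_sum <- fe_ox_sum + co * info$elements[["Fe"]] * info$fe_ox
  }
  list(elements = elements, charge = charge, n_ox = n_ox_sum, fe_ox = fe_ox_sum)
}

#' Check mass, charge and electron balance of a reaction
#'
#' Elements are counted on each side; charge is summed; electron balance
#' compares electrons donated by Fe (total Fe oxidation-state increase,
#' left to right) with electrons accepted by N (total N oxidation-state
#' decrease). O and H are treated as redox-inert, as in the canonical
#' network.
#'
#' @param reaction An `nrfo_reaction`.
#' @return A list of class `nrfo_balance_report` with `element_balanced`
#'   (named logical per element), `charge_balanced`, `electron_balanced`,
#'   `valid` (all flags true) and `discrepancies` — for each failed element
#'   the (left, right) atom counts.
#' @examples
#' check_balance(nrfo_reactions()$chemodenitrification)$valid
#' @export
check_balance <- function(reaction) {
  stopifnot(inherits(reaction, "nrfo_reaction"))
  L <- .side_sums(reaction$reactants)
  R <- .side_sums(reaction$products)
  els <- union(names(L$elements), names(R$elements))
  getel <- function(side, el) if (el %in% names(side$elements)) side$elements[[el]] else 0
  element_balanced <- vapply(els, function(el) {
    isTRUE(all.equal(getel(L, el), getel(R, el)))
  }, logical(1))
  names(element_balanced) <- els
  discrepancies <- lapply(els[!element_balanced], function(el)
    c(left = getel(L, el), right = getel(R, el)))
  names(discrepancies) <- els[!element_balanced]
  charge_balanced <- isTRUE(all.equal(L$charge, R$charge))
  donated <- R$fe_ox - L$fe_ox   # electrons released by Fe oxidation
  accepted <- L$n_ox - R$n_ox    # electrons taken up by N reduction
  electron_balanced <- isTRUE(all.equal(donated, accepted))
  structure(list(
    element_balanced = element_balanced,
    charge_balanced = charge_balanced,
    electron_balanced = electron_balanced,
    electrons_donated_fe = donated,
    electrons_accepted_n = accepted,
    discrepancies = discrepancies,
    valid = all(element_balanced) && charge_balanced && electron_balanced
  ), class = "nrfo_balance_report")
}

#' @export
print.nrfo_balance_report <- function(x, ...) {
  cat("balance report: ", if (x$valid) "VALID" else "INVALID", "\n", sep = "")
  cat("  elements:", paste(sprintf("%s=%s", names(x$element_balanced),
                                   x$element_balanced), collapse = " "), "\n")
  cat(sprintf("  charge=%s electrons=%s (Fe donates %g, N accepts %g)\n",
              x$charge_balanced, x$electron_balanced,
              x$electrons_donated_fe, x$electrons_accepted_n))
  invisible(x)
}

# ---- conversion ratios -----------------------------------------------------

#' Fe(II) oxidized per nitrate reduced enzymatically
#'
#' The coefficient ratio Fe2+/NO3- of the enzymatic NRFO reaction: 2 mol
#' Fe(II) are oxidized per mol nitrate reduced to nitrite when Fe(II) is
#' the sole electron donor. This is the conversion factor the mass-balance
#' partition applies to the excess nitrate consumption.
#'
#' @return Exact numeric ratio (2).
#' @examples
#' fe_per_nitrate_enzymatic()
#' @export
fe_per_nitrate_enzymatic <- function() {
  eq1 <- nrfo_reactions()$enzymatic
  .rat_value(.rat_div(eq1$reactants[["Fe2+"]], eq1$reactants[["NO3-"]]))
}

#' Conversion ratios of chemodenitrification
#'
#' Exact coefficient ratios of the abiotic nitrite + Fe(II) reaction:
#' Fe(II) oxidized per nitrite reduced (2), N2O produced per nitrite
#' reduced (1/2), and Fe(II) oxidized per N2O produced (4). The last one
#' converts the estimated abiotic Fe(II) pool into a predicted
#' chemodenitrification N2O yield.
#'
#' @return Named list `fe_per_nitrite`, `n2o_per_nitrite`, `fe_per_n2o`.
#' @examples
#' chem_ratios()$fe_per_n2o
#' @export
chem_ratios <- function() {
  eq2 <- nrfo_reactions()$chemodenitrification
  fe  <- eq2$reactants[["Fe2+"]]
  no2 <- eq2$reactants[["NO2-"]]
  n2o <- eq2$products[["N2O"]]
  list(
    fe_per_nitrite  = .rat_value(.rat_div(fe, no2)),
    n2o_per_nitrite = .rat_value(.rat_div(n2o, no2)),
    fe_per_n2o      = .rat_value(.rat_div(fe, n2o))
  )
}
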