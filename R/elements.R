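# Element reference data used by the codec: standard atomic weights, default
# valence sets, and metal flags. Covers the 67 elements of the default
# vocabulary (68 atom types including the reserved no-atom slot).

.element_table <- local({
  sym <- c(
    # organics / main group
    "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
    "Se", "As", "Ge", "Sn", "Sb", "Te", "Pb", "Bi", "Al", "Ga", "In", "Tl",
    # s-block
    "Li", "Na", "K", "Rb", "Cs", "Be", "Mg", "Ca", "Sr", "Ba",
    # transition metals + lanthanides common in catalysis
    "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
    "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
    "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
    "La", "Ce", "Nd", "Sm"
  )
  mass <- c(
    1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 28.085, 30.974, 32.06,
    35.45, 79.904, 126.904,
    78.971, 74.922, 72.630, 118.710, 121.760, 127.60, 207.2, 208.980,
    26.982, 69.723, 114.818, 204.38,
    6.94, 22.990, 39.098, 85.468, 132.905, 9.012, 24.305, 40.078, 87.62,
    137.327,
    44.956, 47.867, 50.942, 51.996, 54.938, 55.845, 58.933, 58.693, 63.546,
    65.38,
    88.906, 91.224, 92.906, 95.95, 98.0, 101.07, 102.906, 106.42, 107.868,
    112.414,
    178.49, 180.948, 183.84, 186.207, 190.23, 192.217, 195.084, 196.967,
    200.592,
    138.905, 140.116, 144.242, 150.36
  )
  metal <- !(sym %in% c(
    "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
    "Se", "As", "Ge", "Te"
  ))
  stopifnot(length(sym) == 67L, length(mass) == 67L)
  data.frame(symbol = sym, mass = mass, metal = metal,
             stringsAsFactors = FALSE)
})

# Allowed valence sets (sum of bond orders, aromatic = 1.5) at zero formal
# charge. Metals are treated permissively: coordination numbers up to 8.
.valence_sets <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
  Si = 4, P = c(3, 5), S = c(2, 4, 6), Se = c(2, 4, 6), As = c(3, 5),
  Ge = 4, Sn = c(2, 4), Pb = c(2, 4), Sb = c(3, 5), Bi = c(3, 5),
  Te = c(2, 4, 6), Al = 3, Ga = 3, In = 3, Tl = c(1, 3),
  Li = 1, Na = 1, K = 1, Rb = 1, Cs = 1, Be = 2, Mg = 2, Ca = 2,
  Sr = 2, Ba = 2
)

element_mass <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}

is_metal <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  ifelse(is.na(i), FALSE, .element_table$metal[i])
}

# Maximum total bond order an atom may carry at a given formal charge.
# For main-group elements the usual organic conventions apply: +1 on N/P/O
# raises capacity by one, -1 on B raises it by one, -1 on O/S lowers it.
max_valence <- function(symbol, charge = 0L) {
  v <- .valence_sets[[symbol]]
  if (is.null(v)) return(8)            # metals: loose coordination cap
  vmax <- max(v)
  if (symbol %in% c("N", "P", "O", "S") && charge > 0) vmax <- vmax + charge
  if (symbol %in% c("B") && charge < 0) vmax <- vmax - charge
  if (symbol %in% c("O", "S", "N") && charge < 0) vmax <- vmax + charge
  max(vmax, 0)
}
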