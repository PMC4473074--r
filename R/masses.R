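# Monoisotopic atomic masses, IUPAC/CIAAW 2021 recommended values (Da).
.atomic_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  K  = 38.9637064864
)
.electron_mass <- 0.00054857990907

# Dehydrated glycosidic residue formulas: the mass each residue adds to the
# chain (free monosaccharide minus H2O).
.residue_formulas <- list(
  Hex    = c(C = 6,  H = 10, N = 0, O = 5),
  HexNAc = c(C = 8,  H = 13, N = 1, O = 5),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

# A-series glycan compositions (Hex, HexNAc, NeuAc counts).
.series_residues <- list(
  GM3  = c(hex = 2, hexnac = 0, neuac = 1),
  GM2  = c(hex = 2, hexnac = 1, neuac = 1),
  GM1  = c(hex = 3, hexnac = 1, neuac = 1),
  GD1a = c(hex = 3, hexnac = 1, neuac = 2)
)

.adduct_names <- c("[M-H]-", "[M-2H+Na]-", "[M-2H+K]-")

.formula_mass <- function(formula) {
  stopifnot(all(names(formula) %in% names(.atomic_masses)))
  sum(.atomic_masses[names(formula)] * formula)
}

# Parse an acyl chain label like "18:0" into carbons and double bonds.
.parse_chain <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)[[1]]
  n <- suppressWarnings(as.integer(parts))
  if (length(n) != 2L || anyNA(n) || n[1] < 2L || n[2] < 0L) {
    stop("malformed chain label: '", label, "' (expected e.g. '18:0')",
         call. = FALSE)
  }
  c(carbons = n[1], unsat = n[2])
}

# Elemental formula of a ceramide: sphingoid base dX:1 (C_X H_{2X+1} N O2)
# amide-linked to a fatty acyl chain (condensation loses H2O).
.ceramide_formula <- function(base, acyl = "18:0") {
  if (!base %in% c("d18:1", "d20:1")) {
    stop("unknown ceramide base '", base, "' (supported: d18:1, d20:1)",
         call. = FALSE)
  }
  nb <- .parse_chain(sub("^d", "", base))
  na <- .parse_chain(acyl)
  c(C = nb[["carbons"]] + na[["carbons"]],
    H = (2 * nb[["carbons"]] + 1 - 2 * (nb[["unsat"]] - 1)) +
        (2 * na[["carbons"]] - 2 * na[["unsat"]]) - 2,
    N = 1,
    O = 2 + 2 - 1)
}

#' Define an A-series ganglioside species
#'
#' Constructs the compositional description of one neutral ganglioside
#' molecule: the glycan residue counts implied by the series name plus a
#' ceramide (sphingoid base and N-acyl chain).
#'
#' @param name One of `"GM3"`, `"GM2"`, `"GM1"`, `"GD1a"`. The name fixes the
#'   residue composition: GM3 is 2 Hex + 1 NeuAc on ceramide, GM2 adds a
#'   HexNAc, GM1 adds a further Hex, and GD1a adds a second NeuAc.
#' @param ceramide Sphingoid base label, `"d18:1"` or `"d20:1"`. The two
#'   differ by one C2H4 unit.
#' @param acyl N-acyl chain label; default `"18:0"` (stearoyl), the dominant
#'   acyl chain of adult brain gangliosides.
#' @return An object of class `"ganglioside"`: a list with elements `name`,
#'   `residues` (named counts), `ceramide`, `acyl`.
#' @examples
#' ganglioside("GM2", "d18:1")
#' @export
ganglioside <- function(name, ceramide = "d18:1", acyl = "18:0") {
  if (!name %in% names(.series_residues)) {
    stop("unknown ganglioside species '", name,
         "' (supported: ", paste(names(.series_residues), collapse = ", "),
         ")", call. = FALSE)
  }
  res <- .series_residues[[name]]
  # A-series species with a HexNAc must carry the lactosylceramide core
  stopifnot(res[["hexnac"]] == 0 || res[["hex"]] >= 2)
  .ceramide_formula(ceramide, acyl)  # validates labels
  structure(
    list(name = name, residues = res, ceramide = ceramide, acyl = acyl),
    class = "ganglioside"
  )
}

#' @export
print.ganglioside <- function(x, ...) {
  cat(sprintf("%s (%s/%s): %d Hex, %d HexNAc, %d NeuAc; M = %.4f Da\n",
              x$name, x$ceramide, x$acyl,
              x$residues[["hex"]], x$residues[["hexnac"]],
              x$residues[["neuac"]], neutral_mass(x)))
  invisible(x)
}

#' Theoretical monoisotopic neutral mass of a ganglioside
#'
#' Sums the monoisotopic mass of the ceramide and the dehydrated residue
#' masses of each glycosidic unit (Hex 162.0528, HexNAc 203.0794, NeuAc
#' 291.0954 Da).
#'
#' @param species A [ganglioside()] object.
#' @return Monoisotopic mass in Da.
#' @export
neutral_mass <- function(species) {
  stopifnot(inherits(species, "ganglioside"))
  cer <- .formula_mass(.ceramide_formula(species$ceramide, species$acyl))
  res <- species$residues
  cer +
    res[["hex"]]    * .formula_mass(.residue_formulas$Hex) +
    res[["hexnac"]] * .formula_mass(.residue_formulas$HexNAc) +
    res[["neuac"]]  * .formula_mass(.residue_formulas$NeuAc)
}

#' Negative-mode adduct m/z of a ganglioside ion
#'
#' Computes the theoretical m/z of a singly charged anion: deprotonated
#' `[M-H]-`, sodiated `[M-2H+Na]-`, or potassiated `[M-2H+K]-`. All panel
#' ions carry charge -1; electron mass is included.
#'
#' @param species A [ganglioside()] object.
#' @param adduct One of `"[M-H]-"`, `"[M-2H+Na]-"`, `"[M-2H+K]-"`.
#' @param window Integration half-width around the theoretical m/z (Da);
#'   default 0.5 Da, isolating the monoisotopic peak at reflectron-TOF
#'   resolution.
#' @return A one-row data frame (an ion record) with columns `ion`,
#'   `species`, `ceramide`, `adduct`, `mz`, `window`, `charge`.
#' @examples
#' adduct_mz(ganglioside("GM3", "d18:1"), "[M-H]-")
#' @export
adduct_mz <- function(species, adduct = "[M-H]-", window = 0.5) {
  stopifnot(inherits(species, "ganglioside"), length(adduct) == 1L)
  if (!adduct %in% .adduct_names) {
    stop("unsupported adduct '", adduct, "'; supported singly charged ",
         "anions: ", paste(.adduct_names, collapse = ", "), call. = FALSE)
  }
  if (window <= 0) stop("window half-width must be positive", call. = FALSE)
  m <- neutral_mass(species)
  h <- .atomic_masses[["H"]]
  delta <- switch(adduct,
    "[M-H]-"     = -h,
    "[M-2H+Na]-" = -2 * h + .atomic_masses[["Na"]],
    "[M-2H+K]-"  = -2 * h + .atomic_masses[["K"]]
  )
  mz <- m + delta + .electron_mass  # |charge| = 1
  data.frame(
    ion = paste(species$name, species$ceramide, adduct),
    species = species$name,
    ceramide = species$ceramide,
    adduct = adduct,
    mz = mz,
    window = window,
    charge = -1L,
    stringsAsFactors = FALSE
  )
}

#' Default ion panel configuration
#'
#' The shipped panel quantifies GM3, GM2 and GM1 (both ceramides) as
#' deprotonated ions, and GD1a (both ceramides) as its sodium and potassium
#' adducts; the doubly charged GD1a anion is not observed in tissue and is
#' not supported.
#'
#' @param window Integration half-width (Da).
#' @param acyl N-acyl chain label shared by the panel.
#' @return A list suitable for [build_panel()], with elements `window`,
#'   `acyl` and `ions` (one entry per species giving `ceramides` and
#'   `adducts`).
#' @export
default_panel_config <- function(window = 0.5, acyl = "18:0") {
  list(
    window = window,
    acyl = acyl,
    ions = list(
      list(species = "GM3",  ceramides = c("d18:1", "d20:1"),
           adducts = "[M-H]-"),
      list(species = "GM2",  ceramides = c("d18:1", "d20:1"),
           adducts = "[M-H]-"),
      list(species = "GM1",  ceramides = c("d18:1", "d20:1"),
           adducts = "[M-H]-"),
      list(species = "GD1a", ceramides = c("d18:1", "d20:1"),
           adducts = c("[M-2H+Na]-", "[M-2H+K]-"))
    )
  )
}

#' Build the ion panel table
#'
#' Expands a panel configuration into one row per ion channel with its
#' theoretical m/z and integration window, sorted by m/z. Overlapping
#' integration windows are a configuration error.
#'
#' @param config A list as returned by [default_panel_config()], or a path
#'   to a YAML file with the same structure.
#' @return A data frame of class `"ion_panel"`; the default configuration
#'   yields 10 ions.
#' @examples
#' build_panel()
#' @export
build_panel <- function(config = default_panel_config()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$ions))
  window <- if (is.null(config$window)) 0.5 else as.numeric(config$window)
  acyl <- if (is.null(config$acyl)) "18:0" else config$acyl
  rows <- list()
  for (entry in config$ions) {
    for (cer in entry$ceramides) {
      sp <- ganglioside(entry$species, cer, acyl)
      for (ad in entry$adducts) {
        rows[[length(rows) + 1L]] <- adduct_mz(sp, ad, window)
      }
    }
  }
  panel <- do.call(rbind, rows)
  panel <- panel[order(panel$mz), , drop = FALSE]
  rownames(panel) <- NULL
  if (anyDuplicated(panel$ion)) {
    stop("duplicate ion channels in panel configuration", call. = FALSE)
  }
  # adjacent channels must not share m/z territory
  if (nrow(panel) > 1L) {
    lo <- panel$mz - panel$window
    hi <- panel$mz + panel$window
    bad <- which(hi[-nrow(panel)] >= lo[-1L])
    if (length(bad)) {
      stop(sprintf(
        "integration windows overlap between '%s' and '%s'",
        panel$ion[bad[1L]], panel$ion[bad[1L] + 1L]), call. = FALSE)
    }
  }
  class(panel) <- c("ion_panel", "data.frame")
  panel
}

#' @export
print.ion_panel <- function(x, digits = 4, ...) {
  cat(sprintf("Ion panel: %d channels, window half-width %g Da\n",
              nrow(x), x$window[1L]))
  df <- data.frame(ion = x$ion, mz = round(x$mz, digits),
                   window = x$window)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
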