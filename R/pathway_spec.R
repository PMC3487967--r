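#' Declarative EGFR-signaling / cell-cycle reaction network
#'
#' A `pathway_spec` bundles a list of molecular species, a table of signed
#' rate-law terms, named rate constants and a reference initial condition.
#' Each table row is one reaction term: an optional mass-action factor
#' (product of species concentrations raised to exponents), an optional
#' Michaelis-Menten factor `S/(K + S)`, a named rate constant, and a signed
#' stoichiometry saying which species the term produces or consumes.  The
#' per-species derivative is the sum of all signed term contributions
#' (production minus consumption).
#'
#' @param species character vector of species names.
#' @param reactions data frame with columns `reaction`, `rate_param`,
#'   `factors` (e.g. `"TGFa:1,EGFR:1"`, empty for a constant-rate term),
#'   `mm_species`, `mm_k` (a parameter name; both empty when the term has no
#'   saturating factor) and `stoich` (e.g. `"TGFa:-1,EGFR:-1,Cplx:1"`).
#' @param params named numeric vector of rate constants (finite, >= 0).
#' @param initial named numeric vector, one reference concentration per
#'   species (>= 0).
#' @param aliases named character vector mapping shorthand parameter names
#'   (`X1`, `X2`, `X6`, ...) to species whose initial concentration they
#'   denote in sensitivity/robustness scans.
#' @return an object of class `pathway_spec`.
#' @seealso [default_pathway()], [read_rate_table()], [integrate_pathway()]
#' @export
pathway_spec <- function(species, reactions, params, initial,
                         aliases = c(X1 = "TGFa", X2 = "EGFR", X6 = "PLCg")) {
  stopifnot(is.character(species), length(species) >= 1,
            !anyDuplicated(species), is.data.frame(reactions))
  needed <- c("reaction", "rate_param", "factors", "mm_species", "mm_k",
              "stoich")
  if (!all(needed %in% names(reactions)))
    stop("rate table must have columns: ", paste(needed, collapse = ", "))
  if (is.null(names(params)) || any(names(params) == ""))
    stop("all rate constants must be named")
  if (any(!is.finite(params)) || any(params < 0))
    stop("rate constants must be finite and >= 0")
  if (!setequal(names(initial), species))
    stop("initial condition must name every species exactly once")
  if (any(initial < 0)) stop("initial concentrations must be >= 0")
  initial <- initial[species]

  spec <- structure(
    list(species = species,
         reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
         params = params, initial = initial, aliases = aliases),
    class = "pathway_spec")
  validate_pathway_spec(spec)
  spec
}

# parse "A:-1,B:2" into named numeric; "" -> empty
parse_pairs <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(numeric(0), character(0)))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(trimws(parts), ":", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed species:coefficient pair in '", s, "'")
  setNames(as.numeric(vapply(kv, `[`, "", 2L)),
           vapply(kv, `[`, "", 1L))
}

format_pairs <- function(x) {
  if (!length(x)) return("")
  paste0(names(x), ":", vapply(x, format, "", digits = 15), collapse = ",")
}

validate_pathway_spec <- function(spec) {
  sp <- spec$species
  touched <- character(0)
  for (r in seq_len(nrow(spec$reactions))) {
    row <- spec$reactions[r, ]
    fac <- parse_pairs(row$factors)
    st <- parse_pairs(row$stoich)
    if (!length(st)) stop("reaction '", row$reaction, "' has empty stoichiometry")
    refs <- c(names(fac), names(st),
              if (nzchar_na(row$mm_species)) row$mm_species)
    unknown <- setdiff(refs, sp)
    if (length(unknown))
      stop("reaction '", row$reaction, "' references undeclared species: ",
           paste(unknown, collapse = ", "))
    if (!row$rate_param %in% names(spec$params))
      stop("reaction '", row$reaction, "' uses unknown rate constant '",
           row$rate_param, "'")
    if (nzchar_na(row$mm_species) && !nzchar_na(row$mm_k))
      stop("reaction '", row$reaction, "' has mm_species but no mm_k")
    if (nzchar_na(row$mm_k) && !row$mm_k %in% names(spec$params))
      stop("reaction '", row$reaction, "' uses unknown saturation constant '",
           row$mm_k, "'")
    touched <- c(touched, refs)
  }
  orphan <- setdiff(sp, touched)
  if (length(orphan))
    stop("species never referenced by any reaction: ",
         paste(orphan, collapse = ", "))
  invisible(spec)
}

nzchar_na <- function(x) !is.na(x) && nzchar(x)

#' Compile a pathway spec into flat arrays for the C integrator
#'
#' @param spec a [pathway_spec()].
#' @param clamp character vector of species whose derivative is held at zero
#'   (externally driven inputs, e.g. `"TGFa"` when the ligand level is imposed
#'   by the extracellular field).
#' @return an opaque list consumed by the compiled kernels.
#' @keywords internal
#' @export
compile_pathway <- function(spec, clamp = character(0)) {
  sp <- spec$species
  idx <- setNames(seq_along(sp) - 1L, sp)   # 0-based
  nt <- nrow(spec$reactions)
  term_k <- numeric(nt)
  fac_ptr <- integer(nt + 1L); fac_sp <- integer(0); fac_ex <- numeric(0)
  mm_sp <- integer(nt); mm_k <- numeric(nt)
  st_ptr <- integer(nt + 1L); st_sp <- integer(0); st_co <- numeric(0)
  for (r in seq_len(nt)) {
    row <- spec$reactions[r, ]
    term_k[r] <- unname(spec$params[[row$rate_param]])
    fac <- parse_pairs(row$factors)
    fac_sp <- c(fac_sp, unname(idx[names(fac)]))
    fac_ex <- c(fac_ex, unname(fac))
    fac_ptr[r + 1L] <- length(fac_sp)
    if (nzchar_na(row$mm_species)) {
      mm_sp[r] <- idx[[row$mm_species]]
      mm_k[r] <- unname(spec$params[[row$mm_k]])
    } else {
      mm_sp[r] <- -1L
      mm_k[r] <- 0
    }
    st <- parse_pairs(row$stoich)
    st_sp <- c(st_sp, unname(idx[names(st)]))
    st_co <- c(st_co, unname(st))
    st_ptr[r + 1L] <- length(st_sp)
  }
  clamped <- sp %in% clamp
  list(n_species = length(sp), term_k = term_k,
       fac_ptr = fac_ptr, fac_sp = fac_sp, fac_ex = fac_ex,
       mm_sp = mm_sp, mm_k = mm_k,
       st_ptr = st_ptr, st_sp = st_sp, st_co = st_co,
       clamped = clamped)
}

#' Read / write a rate-law table
#'
#' Tab-separated text with the columns documented in [pathway_spec()].
#' `read_rate_table()` returns the reactions data frame only; combine it with
#' parameter and initial-condition blocks (e.g. from the run configuration)
#' to build a full spec.
#'
#' @param path file path.
#' @return data frame of reactions.
#' @export
read_rate_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                   na.strings = NULL)
  needed <- c("reaction", "rate_param", "factors", "mm_species", "mm_k",
              "stoich")
  if (!all(needed %in% names(df)))
    stop("rate table ", path, " must have columns: ",
         paste(needed, collapse = ", "))
  df[needed]
}

#' @rdname read_rate_table
#' @param reactions reactions data frame.
#' @export
write_rate_table <- function(reactions, path) {
  write.table(reactions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default EGFR-signaling + cell-cycle network
#'
#' The published kinetic tables for this model live in supplementary material
#' that is not distributed with the main text, so the package ships a
#' documented stand-in with the same topology: TGF\eqn{\alpha} binds EGFR,
#' the ligand-receptor complex autophosphorylates (consuming the ligand,
#' i.e. receptor internalization), active receptor is recycled by a
#' saturating phosphatase step (`V4`, `K4`), phosphorylated receptor
#' activates PLC\eqn{\gamma} (`k3`) which relaxes back slowly (`k5`); the
#' receptor also drives cyclin-CDK synthesis in a cell-cycle switch with
#' CDh1/cycCDK antagonism and an exponentially growing mass variable.
#' Division readiness is CDh1 < thr1 and cycCDK > thr2 (strict).
#'
#' Parameter choices are calibrated once, a priori, to the qualitative
#' properties reported for the original network (robust migration potential,
#' ~24 h division period); see the methods vignette.
#'
#' @param params optional named overrides of rate constants.
#' @param initial optional named overrides of initial concentrations.
#' @return a [pathway_spec()].
#' @export
default_pathway <- function(params = NULL, initial = NULL) {
  species <- c("TGFa", "EGFR", "Cplx", "pEGFR", "PLCgi", "PLCg",
               "CDh1", "CDh1i", "cycCDK", "Mass")
  reactions <- data.frame(
    reaction   = c("bind", "unbind", "phos", "dephos", "plc_act", "plc_rel",
                   "growth", "crowding", "cdk_syn", "cdk_deg",
                   "cdk_deg_cdh1", "cdh1_act", "cdh1_inact"),
    rate_param = c("k1", "ku", "k2", "V4", "k3", "k5",
                   "kg", "kg2", "kc1", "kc2", "kc2p", "kc3", "kc4"),
    factors    = c("TGFa:1,EGFR:1", "Cplx:1", "Cplx:2", "", "pEGFR:1,PLCgi:1",
                   "PLCg:1", "Mass:1", "Mass:2", "Mass:1", "cycCDK:1",
                   "CDh1:1,cycCDK:1", "", "cycCDK:1"),
    mm_species = c("", "", "", "pEGFR", "", "", "", "", "", "", "",
                   "CDh1i", "CDh1"),
    mm_k       = c("", "", "", "K4", "", "", "", "", "", "", "",
                   "J3", "J4"),
    stoich     = c("TGFa:-1,EGFR:-1,Cplx:1",
                   "TGFa:1,EGFR:1,Cplx:-1",
                   "Cplx:-2,pEGFR:2",
                   "pEGFR:-1,EGFR:1,TGFa:1",
                   "PLCgi:-1,PLCg:1",
                   "PLCg:-1,PLCgi:1",
                   "Mass:1",
                   "Mass:-1",
                   "cycCDK:1",
                   "cycCDK:-1",
                   "cycCDK:-1",
                   "CDh1i:-1,CDh1:1",
                   "CDh1:-1,CDh1i:1"),
    stringsAsFactors = FALSE)
  p <- c(k1 = 1.2, ku = 0.3, k2 = 3, V4 = 1.0, K4 = 0.3,
         k3 = 1.5, k5 = 2e-4,
         kg = 0.07, kg2 = 0.0175, kc1 = 0.06, kc2 = 0.02, kc2p = 1,
         kc3 = 0.2, J3 = 0.05, kc4 = 2.2, J4 = 0.05)
  init <- c(TGFa = 0.4, EGFR = 0.3, Cplx = 0, pEGFR = 0, PLCgi = 1,
            PLCg = 0.01, CDh1 = 0.9, CDh1i = 0.1, cycCDK = 0.01, Mass = 1)
  if (!is.null(params)) {
    stopifnot(all(names(params) %in% names(p)))
    p[names(params)] <- params
  }
  if (!is.null(initial)) {
    stopifnot(all(names(initial) %in% names(init)))
    init[names(initial)] <- initial
  }
  pathway_spec(species, reactions, p, init)
}
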