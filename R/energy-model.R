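# Nearest-neighbor thermodynamics: base-stack free energies from tabulated
# (dH, dG37) pairs, loop free energies from size-keyed entropy tables with
# Jacobson-Stockmayer log extrapolation, and an affine multiloop model.

.T0 <- 310.15          # 37 C reference, Kelvin
.KB <- 0.0019872       # kcal/(mol K), molar Boltzmann (gas) constant
.EINF <- 1e6           # "forbidden" sentinel, kcal/mol; Boltzmann weight
                       # underflows to exactly 0, so it propagates safely

.BASES <- c("A", "C", "G", "U")
.CANONICAL <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Load thermodynamic parameters at a folding temperature
#'
#' Reads a sectioned plain-text parameter file (sections `STACK`,
#' `HAIRPIN`, `BULGE`, `INTERNAL`, `MULTILOOP`, `MAXLOOP`) and resolves it
#' at the requested temperature. Stack free energies are computed as
#' `dG(T) = dH - T*dS` with `dS` derived from the tabulated `(dH, dG37)`
#' pair. Loop tables carry no enthalpy and are treated as purely entropic:
#' `G(T) = (T/310.15) * G(37C)`. Beyond the largest tabulated loop size the
#' Jacobson-Stockmayer form `G(n) = G(nmax) + 1.75*kB*T*ln(n/nmax)`
#' applies.
#'
#' @param parameters Path to a parameter file, or the built-in tag
#'   `"turner2004"` (the packaged Turner 2004 set).
#' @param temperature_celsius Folding temperature in degrees Celsius
#'   (default 37; accepted range -50..150).
#' @return An object of class `circfold_energy`: stack `dH`/`dS` arrays
#'   indexed by the four stack bases, loop tables, multiloop coefficients
#'   `(a, b, c)`, `temperature` (Kelvin), `kB`, and `max_tabulated_loop`.
#' @examples
#' m <- load_parameters("turner2004", 37)
#' stack_free_energy(m, c("G", "C"), c("C", "G"))
#' @export
load_parameters <- function(parameters = "turner2004",
                            temperature_celsius = 37) {
  if (!is.numeric(temperature_celsius) || length(temperature_celsius) != 1L ||
      is.na(temperature_celsius) ||
      temperature_celsius < -50 || temperature_celsius > 150)
    stop("temperature must be a single value between -50 and 150 degrees Celsius",
         call. = FALSE)
  path <- parameters
  if (identical(parameters, "turner2004"))
    path <- system.file("extdata", "turner2004.par", package = "circfold",
                        mustWork = TRUE)
  if (!file.exists(path))
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  raw <- readLines(path)
  tab <- .parse_param_file(raw, path)

  # required stack keys: all ordered canonical pair-of-pairs
  need <- character(0)
  for (op in .CANONICAL) for (ip in .CANONICAL)
    need <- c(need, paste0(substr(op, 1, 1), substr(ip, 1, 1), "/",
                           substr(op, 2, 2), substr(ip, 2, 2)))
  missing <- setdiff(need, names(tab$stack))
  if (length(missing) > 0L)
    stop(sprintf("parameter file %s is missing stack key(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)

  dH <- array(NA_real_, c(4, 4, 4, 4), dimnames = rep(list(.BASES), 4))
  dS <- dH
  for (key in need) {
    v <- tab$stack[[key]]
    o5 <- substr(key, 1, 1); i5 <- substr(key, 2, 2)
    o3 <- substr(key, 4, 4); i3 <- substr(key, 5, 5)
    dH[o5, o3, i5, i3] <- v[1]
    dS[o5, o3, i5, i3] <- (v[1] - v[2]) / .T0
  }
  # symmetry under 5'->3' relabeling: O5 I5 / O3 I3  <->  I3 O3 / I5 O5
  for (key in need) {
    o5 <- substr(key, 1, 1); i5 <- substr(key, 2, 2)
    o3 <- substr(key, 4, 4); i3 <- substr(key, 5, 5)
    if (abs(dH[o5, o3, i5, i3] - dH[i3, i5, o3, o5]) > 1e-9)
      stop(sprintf("stack table violates strand-flip symmetry at key %s", key),
           call. = FALSE)
  }

  T <- temperature_celsius + 273.15
  structure(list(
    stack_dH = dH, stack_dS = dS,
    hairpin_g37 = tab$hairpin, bulge_g37 = tab$bulge,
    internal_g37 = tab$internal,
    multiloop = tab$multiloop,           # c(a, b, c) at 37 C
    max_tabulated_loop = tab$maxloop,
    temperature = T, temperature_celsius = temperature_celsius,
    kB = .KB, parameter_file = path),
    class = "circfold_energy")
}

.parse_param_file <- function(raw, path) {
  section <- NULL
  stack <- list()
  loops <- list(HAIRPIN = numeric(0), BULGE = numeric(0),
                INTERNAL = numeric(0))
  multiloop <- NULL
  maxloop <- NA_integer_
  for (ln in seq_along(raw)) {
    line <- sub("#.*$", "", raw[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    if (toks[1] %in% c("STACK", "HAIRPIN", "BULGE", "INTERNAL")) {
      section <- toks[1]
      next
    }
    if (toks[1] == "MULTILOOP") {
      v <- suppressWarnings(as.numeric(toks[-1]))
      if (length(v) != 3L || anyNA(v))
        stop(sprintf("%s line %d: MULTILOOP needs 3 numeric coefficients",
                     basename(path), ln), call. = FALSE)
      multiloop <- v
      next
    }
    if (toks[1] == "MAXLOOP") {
      maxloop <- suppressWarnings(as.integer(toks[2]))
      next
    }
    if (is.null(section))
      stop(sprintf("%s line %d: data before any section header",
                   basename(path), ln), call. = FALSE)
    if (section == "STACK") {
      if (length(toks) != 3L || !grepl("^[ACGU]{2}/[ACGU]{2}$", toks[1]))
        stop(sprintf("%s line %d: malformed STACK entry '%s'",
                     basename(path), ln, raw[ln]), call. = FALSE)
      v <- suppressWarnings(as.numeric(toks[2:3]))
      if (anyNA(v))
        stop(sprintf("%s line %d: non-numeric stack energies",
                     basename(path), ln), call. = FALSE)
      stack[[toks[1]]] <- v
    } else {
      if (length(toks) != 2L)
        stop(sprintf("%s line %d: malformed %s entry", basename(path), ln,
                     section), call. = FALSE)
      sz <- suppressWarnings(as.integer(toks[1]))
      v <- suppressWarnings(as.numeric(toks[2]))
      if (is.na(sz) || is.na(v))
        stop(sprintf("%s line %d: non-numeric %s entry", basename(path), ln,
                     section), call. = FALSE)
      loops[[section]][sz] <- v
    }
  }
  if (is.null(multiloop))
    stop(sprintf("%s: missing MULTILOOP section", basename(path)),
         call. = FALSE)
  if (is.na(maxloop)) maxloop <- max(which(!is.na(loops$HAIRPIN)))
  hp <- loops$HAIRPIN
  if (length(hp) < 3L || anyNA(hp[3:length(hp)]))
    stop(sprintf("%s: hairpin table must cover all sizes 3..%d",
                 basename(path), length(hp)), call. = FALSE)
  bg <- loops$BULGE
  if (length(bg) < 1L || anyNA(bg))
    stop(sprintf("%s: bulge table must cover sizes 1..%d", basename(path),
                 length(bg)), call. = FALSE)
  il <- loops$INTERNAL
  if (length(il) < 2L || anyNA(il[2:length(il)]))
    stop(sprintf("%s: internal table must cover sizes 2..%d", basename(path),
                 length(il)), call. = FALSE)
  list(stack = stack, hairpin = hp, bulge = bg, internal = il,
       multiloop = multiloop, maxloop = maxloop)
}

#' @export
print.circfold_energy <- function(x, ...) {
  cat(sprintf("circfold energy model: %s at %.2f K (%.1f C)\n",
              basename(x$parameter_file), x$temperature,
              x$temperature_celsius))
  cat(sprintf("  %d canonical stacks; loops tabulated to size %d (log-extrapolated beyond)\n",
              sum(!is.na(x$stack_dH)), x$max_tabulated_loop))
  cat(sprintf("  multiloop: a=%.2f b=%.2f c=%.2f kcal/mol (37 C values)\n",
              x$multiloop[1], x$multiloop[2], x$multiloop[3]))
  invisible(x)
}

.as_pair <- function(p) {
  if (is.character(p) && length(p) == 1L && nchar(p) == 2L)
    p <- c(substr(p, 1, 1), substr(p, 2, 2))
  p <- toupper(p)
  p[p == "T"] <- "U"
  if (length(p) != 2L || !all(p %in% .BASES))
    stop("a base pair must be two bases from {A,C,G,U}", call. = FALSE)
  p
}

#' Free energy of a base stack
#'
#' Returns `dH - T*dS` for the stack formed by `pair2` stacking directly
#' inside `pair1`. Pairs are given 5'-base first: `pair1 = c("G","C")`,
#' `pair2 = c("C","G")` is the 5'GC/3'CG stack. Values are symmetric under
#' the standard strand-flip relabeling.
#'
#' @param model A [load_parameters()] energy model.
#' @param pair1 Outer (closing) pair, 5' base first; `"GC"` shorthand works.
#' @param pair2 Inner pair stacked immediately inside `pair1`.
#' @return Stack free energy at the model temperature, kcal/mol.
#' @export
stack_free_energy <- function(model, pair1, pair2) {
  stopifnot(inherits(model, "circfold_energy"))
  p1 <- .as_pair(pair1); p2 <- .as_pair(pair2)
  if (!paste0(p1, collapse = "") %in% .CANONICAL)
    stop(sprintf("pair %s-%s is not canonical", p1[1], p1[2]), call. = FALSE)
  if (!paste0(p2, collapse = "") %in% .CANONICAL)
    stop(sprintf("pair %s-%s is not canonical", p2[1], p2[2]), call. = FALSE)
  dh <- model$stack_dH[p1[1], p1[2], p2[1], p2[2]]
  ds <- model$stack_dS[p1[1], p1[2], p2[1], p2[2]]
  dh - model$temperature * ds
}

#' Describe a loop for energy evaluation
#'
#' @param kind One of `"hairpin"`, `"internal"`, `"bulge"`, `"multiloop"`,
#'   `"circular_exterior"`.
#' @param unpaired_count Total unpaired nucleotides in the loop.
#' @param branch_count Number of helices bordering the loop (a hairpin has
#'   1; internal/bulge 2; multiloop >= 3). The circular exterior face is
#'   re-classified by its branch count before scoring.
#' @param sizes For 2-branch loops, the two unpaired strand lengths
#'   `c(s1, s2)`; required to distinguish bulge from internal when
#'   `kind = "circular_exterior"`.
#' @return A `circfold_loop` descriptor.
#' @export
loop_descriptor <- function(kind, unpaired_count, branch_count = NULL,
                            sizes = NULL) {
  kind <- match.arg(kind, c("hairpin", "internal", "bulge", "multiloop",
                            "circular_exterior"))
  if (is.null(branch_count))
    branch_count <- switch(kind, hairpin = 1L, internal = 2L, bulge = 2L,
                           multiloop = 3L, circular_exterior = 1L)
  ok <- switch(kind,
               hairpin = branch_count == 1L,
               internal = branch_count == 2L,
               bulge = branch_count == 2L,
               multiloop = branch_count >= 3L,
               circular_exterior = branch_count >= 0L)
  if (!ok)
    stop(sprintf("branch_count %d is inconsistent with a %s loop",
                 branch_count, kind), call. = FALSE)
  if (!is.null(sizes) && sum(sizes) != unpaired_count)
    stop("strand sizes must sum to unpaired_count", call. = FALSE)
  structure(list(kind = kind, unpaired_count = as.integer(unpaired_count),
                 branch_count = as.integer(branch_count), sizes = sizes),
            class = "circfold_loop")
}

# size-keyed loop energy with entropic temperature rescaling and
# Jacobson-Stockmayer extrapolation beyond the tabulated range
.loop_size_energy <- function(model, table37, n, min_size) {
  if (n < min_size) return(.EINF)
  sc <- model$temperature / .T0
  m <- model$max_tabulated_loop
  if (n <= m && n <= length(table37) && !is.na(table37[n]))
    return(sc * table37[n])
  base <- sc * table37[min(m, length(table37))]
  base + 1.75 * model$kB * model$temperature * log(n / min(m, length(table37)))
}

#' Free energy of a loop element
#'
#' Hairpin, bulge and internal loops are scored from the size-keyed tables
#' (entropically rescaled to the model temperature, log-extrapolated beyond
#' the tabulated maximum); multiloops use the affine form
#' `a + b*branch_count + c*unpaired_count`. Hairpins below 3 unpaired nt
#' return the forbidden sentinel (`1e6` kcal/mol). The circular exterior
#' face is re-classified by its branch count: 1 scores as a hairpin, 2 as
#' internal/bulge, 3 or more as a multiloop; with no branches it is the
#' open circle, energy 0.
#'
#' @param model A [load_parameters()] energy model.
#' @param loop A [loop_descriptor()].
#' @return Free energy in kcal/mol.
#' @export
loop_free_energy <- function(model, loop) {
  stopifnot(inherits(model, "circfold_energy"), inherits(loop, "circfold_loop"))
  kind <- loop$kind
  bc <- loop$branch_count
  if (kind == "circular_exterior") {
    if (bc == 0L) return(0)
    kind <- if (bc == 1L) "hairpin"
            else if (bc == 2L) {
              if (is.null(loop$sizes))
                stop("2-branch exterior face needs per-strand sizes to classify bulge vs internal",
                     call. = FALSE)
              if (min(loop$sizes) == 0L) "bulge" else "internal"
            } else "multiloop"
  }
  switch(kind,
    hairpin = .loop_size_energy(model, model$hairpin_g37,
                                loop$unpaired_count, 3L),
    bulge = .loop_size_energy(model, model$bulge_g37,
                              loop$unpaired_count, 1L),
    internal = .loop_size_energy(model, model$internal_g37,
                                 loop$unpaired_count, 2L),
    multiloop = {
      sc <- model$temperature / .T0
      ml <- model$multiloop
      sc * (ml[1] + ml[2] * bc + ml[3] * loop$unpaired_count)
    })
}

#' Free energy of a helix
#'
#' The stability of a helix `(i, j, k)` is the sum of its `k - 1` base
#' stack free energies on the given circular sequence; a single pair has no
#' stack and scores 0.
#'
#' @param model A [load_parameters()] energy model.
#' @param helix A [helix()] triple.
#' @param seq A [circ_sequence()].
#' @return Free energy in kcal/mol.
#' @export
helix_free_energy <- function(model, helix, seq) {
  stopifnot(inherits(model, "circfold_energy"), inherits(seq, "circ_sequence"))
  helix <- .as_helix(helix)
  n <- seq$n
  g <- 0
  for (m in seq_len(helix$k) - 1L) {
    p <- .cpos(helix$i + m, n); q <- .cpos(helix$j - m, n)
    if (!.canonical_code(seq$codes[p], seq$codes[q]))
      stop(sprintf("helix pair (%d, %d) is %s-%s, not canonical", p, q,
                   seq$bases[p], seq$bases[q]), call. = FALSE)
    if (m > 0L) {
      po <- .cpos(helix$i + m - 1L, n); qo <- .cpos(helix$j - m + 1L, n)
      g <- g + stack_free_energy(model,
                                 c(seq$bases[po], seq$bases[qo]),
                                 c(seq$bases[p], seq$bases[q]))
    }
  }
  g
}

# precomputed numeric tables handed to the C++ core, resolved at the model
# temperature; hairpin/bulge/internal vectors cover sizes 1..nmax
.engine_par <- function(model, n) {
  stackE <- rep(.EINF, 256)
  for (op in .CANONICAL) for (ip in .CANONICAL) {
    o5 <- substr(op, 1, 1); o3 <- substr(op, 2, 2)
    i5 <- substr(ip, 1, 1); i3 <- substr(ip, 2, 2)
    co5 <- match(o5, .BASES); co3 <- match(o3, .BASES)
    ci5 <- match(i5, .BASES); ci3 <- match(i3, .BASES)
    idx <- (((co5 - 1) * 4 + (co3 - 1)) * 4 + (ci5 - 1)) * 4 + (ci3 - 1) + 1
    stackE[idx] <- model$stack_dH[o5, o3, i5, i3] -
      model$temperature * model$stack_dS[o5, o3, i5, i3]
  }
  nmax <- max(n, model$max_tabulated_loop) + 2L
  hpE <- vapply(seq_len(nmax), function(s)
    .loop_size_energy(model, model$hairpin_g37, s, 3L), numeric(1))
  bgE <- vapply(seq_len(nmax), function(s)
    .loop_size_energy(model, model$bulge_g37, s, 1L), numeric(1))
  inE <- vapply(seq_len(nmax), function(s)
    .loop_size_energy(model, model$internal_g37, s, 2L), numeric(1))
  sc <- model$temperature / .T0
  list(stackE = stackE, hpE = hpE, bulgeE = bgE, intE = inE,
       mlA = sc * model$multiloop[1], mlB = sc * model$multiloop[2],
       mlC = sc * model$multiloop[3],
       kT = model$kB * model$temperature, inf = .EINF,
       maxloop = as.integer(model$max_tabulated_loop))
}
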