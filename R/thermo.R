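# Thermodynamic features of guide RNAs.
#
# An engine is a list of three closures returning minimum free energies in
# kcal/mol at 37 C:
#   monomer(rna)        - self-folding of the guide
#   duplex_rna(a, b)    - RNA:RNA duplex (guide homodimer)
#   duplex_dna(rna,dna) - RNA:DNA hybrid (guide vs target strand)
# Three backends are provided: a constant stub for contract tests, a built-in
# nearest-neighbour model (fast, dependency-free), and the ViennaRNA
# command-line programs where available.

#' Constant-energy stub engine
#'
#' Returns `value` for every query; used to test the feature-passing contract
#' independently of any energy model.
#' @param value energy returned for all queries (kcal/mol)
#' @return engine of class `thermo_engine`
#' @export
thermo_engine_const <- function(value = -1) {
  structure(list(
    name = "const",
    monomer = function(rna) value,
    duplex_rna = function(a, b) value,
    duplex_dna = function(rna, dna) value), class = "thermo_engine")
}

# Sugimoto et al. RNA/DNA hybrid nearest-neighbour stacks (dG37, kcal/mol),
# keyed by the RNA-strand dinucleotide (5'->3'), duplex assumed fully
# complementary.  Initiation +3.1.
.hybrid_stacks <- c(
  AA = -1.0, AC = -2.1, AG = -1.8, AU = -0.9,
  CA = -0.9, CC = -2.1, CG = -1.7, CU = -0.9,
  GA = -1.3, GC = -2.7, GG = -2.9, GU = -1.1,
  UA = -0.6, UC = -1.5, UG = -1.6, UU = -0.2)
.hybrid_init <- 3.1

# Watson-Crick RNA/RNA stacks (Turner dG37, kcal/mol), keyed by the
# dinucleotide on one strand (5'->3'); initiation +4.09.
.rna_stacks <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AU = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CU = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GU = -2.24,
  UA = -1.33, UC = -2.35, UG = -2.11, UU = -0.93)
.rna_init <- 4.09
.hairpin_loop <- 5.0

.to_rna <- function(s) chartr("Tt", "Uu", toupper(s))
.rna_comp <- function(x) chartr("ACGU", "UGCA", x)

# best ungapped antiparallel duplex energy between RNA strands a and b
.best_duplex_rna <- function(a, b) {
  av <- strsplit(.to_rna(a), "")[[1]]
  bv <- strsplit(.to_rna(b), "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- 0
  # antiparallel pairing: a[i] pairs b[j] with i + j constant
  for (s in 2L:(na + nb)) {
    i <- max(1L, s - nb):min(na, s - 1L)
    j <- s - i
    ok <- av[i] == .rna_comp(bv[j])
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= 2L)) {
      seg <- i[starts[k]:ends[k]]
      din <- paste0(av[seg[-length(seg)]], av[seg[-1L]])
      e <- .rna_init + sum(.rna_stacks[din])
      if (e < best) best <- e
    }
  }
  best
}

# best single-hairpin energy of one RNA strand (ungapped stem, loop >= 3)
.best_hairpin <- function(rna) {
  v <- strsplit(.to_rna(rna), "")[[1]]
  n <- length(v)
  best <- 0
  if (n < 7L) return(0)
  for (i in 1L:(n - 6L)) {
    for (j in (i + 6L):n) {
      # grow a stem outward-in from (i, j)
      len <- 0L
      while (i + len < j - len - 3L && v[i + len] == .rna_comp(v[j - len])) {
        len <- len + 1L
      }
      if (len >= 2L) {
        seg <- i:(i + len - 1L)
        din <- paste0(v[seg[-length(seg)]], v[seg[-1L]])
        e <- .hairpin_loop + sum(.rna_stacks[din])
        if (e < best) best <- e
      }
    }
  }
  best
}

#' Built-in nearest-neighbour thermodynamics engine
#'
#' Dependency-free energy model: RNA/DNA hybrids use dinucleotide stacking
#' parameters for perfectly complementary hybrid duplexes, the guide
#' homodimer is the best ungapped antiparallel RNA:RNA duplex, and guide
#' self-folding is the best single ungapped hairpin with a flat loop penalty.
#' All energies are clamped at 0 (no favourable structure).
#'
#' @return engine of class `thermo_engine`
#' @export
thermo_engine_nn <- function() {
  structure(list(
    name = "nearest_neighbour",
    monomer = function(rna) min(0, .best_hairpin(rna)),
    duplex_rna = function(a, b) min(0, .best_duplex_rna(a, b)),
    duplex_dna = function(rna, dna) {
      v <- strsplit(.to_rna(rna), "")[[1]]
      if (length(v) < 2L) return(0)
      din <- paste0(v[-length(v)], v[-1L])
      min(0, .hybrid_init + sum(.hybrid_stacks[din]))
    }), class = "thermo_engine")
}

#' ViennaRNA command-line engine
#'
#' Shells out to `RNAfold` (guide self-folding) and `RNAduplex` (homodimer
#' and guide:target hybrid).  The hybrid is evaluated with RNA parameters on
#' the RNA-ized duplex, an approximation to a dedicated DNA/RNA parameter
#' set.
#'
#' @param rnafold,rnaduplex program names or paths
#' @return engine of class `thermo_engine`
#' @export
thermo_engine_vienna <- function(rnafold = "RNAfold", rnaduplex = "RNAduplex") {
  if (Sys.which(rnafold) == "" || Sys.which(rnaduplex) == "")
    stop("ViennaRNA programs not found on PATH; use thermo_engine_nn() or ",
         "thermo_engine_const() instead", call. = FALSE)
  parse_energy <- function(lines) {
    m <- regmatches(lines, regexpr("\\(\\s*-?[0-9.]+\\s*\\)$", lines))
    m <- m[lengths(m) > 0 | nzchar(m)]
    if (!length(m)) stop("could not parse energy from ViennaRNA output",
                         call. = FALSE)
    as.numeric(gsub("[() ]", "", m[[length(m)]]))
  }
  structure(list(
    name = "vienna",
    monomer = function(rna) {
      out <- system2(rnafold, c("--noPS"), input = .to_rna(rna), stdout = TRUE)
      min(0, parse_energy(out))
    },
    duplex_rna = function(a, b) {
      out <- system2(rnaduplex, stdout = TRUE, stderr = FALSE,
                     input = paste(.to_rna(a), .to_rna(b), sep = "\n"))
      en <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\)", out))
      en <- en[nzchar(en)]
      if (!length(en)) stop("could not parse RNAduplex output", call. = FALSE)
      min(0, as.numeric(gsub("[() ]", "", en[[1]])))
    },
    duplex_dna = function(rna, dna) {
      out <- system2(rnaduplex, stdout = TRUE, stderr = FALSE,
                     input = paste(.to_rna(rna), .to_rna(dna), sep = "\n"))
      en <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\)", out))
      en <- en[nzchar(en)]
      if (!length(en)) stop("could not parse RNAduplex output", call. = FALSE)
      min(0, as.numeric(gsub("[() ]", "", en[[1]])))
    }), class = "thermo_engine")
}

#' Thermodynamic features of one guide
#'
#' Four minimum free energies: guide self-folding, guide homodimer, the
#' guide:target-DNA hybrid over the full 20-nt protospacer, and the hybrid of
#' the 8-nt PAM-proximal seed (guide positions G13-G20) with its target.
#'
#' @param spacer 20-nt guide sequence (DNA alphabet)
#' @param context30 30-nt context (unused by the built-in engines; kept so
#'   engines may condition on flanking sequence)
#' @param engine a `thermo_engine`
#' @return named numeric vector `mfe_monomer`, `mfe_homodimer`, `mfe_hybrid`,
#'   `mfe_seed_hybrid`
#' @export
thermo_features <- function(spacer, context30 = NULL, engine = thermo_engine_nn()) {
  if (!inherits(engine, "thermo_engine"))
    stop("engine must be a thermo_engine (see thermo_engine_nn(), ",
         "thermo_engine_vienna(), thermo_engine_const())", call. = FALSE)
  check_dna(spacer, "spacer")
  guide <- .to_rna(spacer)
  target <- revcomp(spacer)              # template strand the guide anneals to
  seed <- substring(spacer, 13L, 20L)    # 8 nt PAM-proximal
  seed_target <- revcomp(seed)
  c(mfe_monomer = engine$monomer(guide),
    mfe_homodimer = engine$duplex_rna(guide, guide),
    mfe_hybrid = engine$duplex_dna(guide, target),
    mfe_seed_hybrid = engine$duplex_dna(.to_rna(seed), seed_target))
}

thermo_features_matrix <- function(spacers, contexts, engine) {
  out <- t(vapply(seq_along(spacers), function(i)
    thermo_features(spacers[i], contexts[i], engine), numeric(4)))
  colnames(out) <- c("mfe_monomer", "mfe_homodimer", "mfe_hybrid",
                     "mfe_seed_hybrid")
  out
}
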