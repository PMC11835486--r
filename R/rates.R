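#' Per-species reaction rates of the maturation model
#'
#' Bundles the four mass-action rate constants governing the fate of one
#' pre-miRNA species: reversible association with Dicer, irreversible
#' stalling, and cleavage ("dicing") of the bound complex into mature
#' miRNA.
#'
#' @param k_a association rate of free pre-miRNA with free Dicer
#'   (s^-1 nM^-1).
#' @param k_b dissociation rate of the pre-miRNA--Dicer complex (s^-1).
#' @param k_c stalling rate: irreversible sequestration of pre-miRNA and
#'   Dicer into a dead-end complex (s^-1 nM^-1).
#' @param k_d dicing rate: cleavage of the bound complex, releasing mature
#'   miRNA and free Dicer (s^-1).
#'
#' @return An object of class `rate_set`.
#' @export
#' @examples
#' rate_set(k_a = 0.0053, k_b = 0.134, k_c = 0.0122, k_d = 10439)
rate_set <- function(k_a, k_b, k_c, k_d) {
  r <- list(k_a = k_a, k_b = k_b, k_c = k_c, k_d = k_d)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("rate '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("rate '", nm, "' must be >= 0, got ", v, call. = FALSE)
  }
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> k_a=%g /s/nM  k_b=%g /s  k_c=%g /s/nM  k_d=%g /s\n",
              x$k_a, x$k_b, x$k_c, x$k_d))
  invisible(x)
}

#' Published let-7 dicing rate constants
#'
#' Rate constants previously fitted to in vitro dicing kinetics of
#' Drosophila let-7, for the wild-type hairpin and a short-loop mutant
#' that is bound and processed much less efficiently.
#'
#' @param variant `"wt"` for the wild-type hairpin, `"short_loop"` for the
#'   short-loop mutant.
#' @return A [rate_set()].
#' @seealso [let7_kd_ratio()] for the dissociation-constant constraints
#'   used when refitting these parameters.
#' @export
dicing_rates_let7 <- function(variant = c("wt", "short_loop")) {
  variant <- match.arg(variant)
  switch(variant,
    wt         = rate_set(k_a = 0.0053, k_b = 0.1340, k_c = 0.0122, k_d = 10439),
    short_loop = rate_set(k_a = 0.0020, k_b = 0.2902, k_c = 0.0343, k_d = 0.0707)
  )
}

#' Dissociation-constant constraint for let-7 variants
#'
#' Experimentally reported Kd = k_b / k_a (nM) for the wild-type and
#' short-loop let-7 hairpins. Constrained fitting enforces this ratio.
#'
#' @inheritParams dicing_rates_let7
#' @return A single number (nM).
#' @export
let7_kd_ratio <- function(variant = c("wt", "short_loop")) {
  variant <- match.arg(variant)
  c(wt = 25.4, short_loop = 147.7)[[variant]]
}

#' Specify one pre-miRNA species
#'
#' @param label identifier, unique within a [system_config()].
#' @param P0 initial free pre-miRNA concentration (nM).
#' @param rates a [rate_set()].
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(label, P0, rates) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 < 0) {
    stop("'P0' must be a single finite number >= 0", call. = FALSE)
  }
  if (!inherits(rates, "rate_set")) stop("'rates' must be a rate_set", call. = FALSE)
  structure(list(label = label, P0 = P0, rates = rates), class = "species_spec")
}

#' Configure a (possibly multi-species) maturation system
#'
#' @param species a list of [species_spec()] objects (at least one).
#' @param D0 initial free Dicer concentration (nM).
#' @param shared_dicer if `TRUE` all species draw on one shared Dicer pool
#'   (competition); if `FALSE` each species is simulated in isolation with
#'   the full `D0` to itself (the no-competition control).
#' @return An object of class `system_config`.
#' @export
#' @examples
#' cfg <- system_config(
#'   list(species_spec("let7", 1, dicing_rates_let7("wt"))),
#'   D0 = 5
#' )
system_config <- function(species, D0, shared_dicer = TRUE) {
  if (inherits(species, "species_spec")) species <- list(species)
  if (!is.list(species) || length(species) < 1L ||
      !all(vapply(species, inherits, logical(1), "species_spec"))) {
    stop("'species' must be a non-empty list of species_spec objects",
         call. = FALSE)
  }
  labs <- vapply(species, `[[`, character(1), "label")
  if (anyDuplicated(labs)) {
    stop("species labels must be unique: duplicated ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(D0) || length(D0) != 1L || !is.finite(D0) || D0 < 0) {
    stop("'D0' must be a single finite number >= 0", call. = FALSE)
  }
  stopifnot(is.logical(shared_dicer), length(shared_dicer) == 1L)
  structure(list(species = species, D0 = D0, shared_dicer = shared_dicer),
            class = "system_config")
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf("<system_config> %d species, D0=%g nM, %s Dicer pool\n",
              length(x$species), x$D0,
              if (x$shared_dicer) "shared" else "isolated"))
  invisible(x)
}

# rate matrix (n x 4) and P0/label vectors, used by the integrator
config_rates <- function(config) {
  n <- length(config$species)
  m <- matrix(0, n, 4, dimnames = list(NULL, c("k_a", "k_b", "k_c", "k_d")))
  for (i in seq_len(n)) m[i, ] <- unlist(config$species[[i]]$rates)
  m
}

config_P0 <- function(config) {
  vapply(config$species, `[[`, numeric(1), "P0")
}

config_labels <- function(config) {
  vapply(config$species, `[[`, character(1), "label")
}
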