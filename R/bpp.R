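# Watson-Crick + wobble pairing predicate on single bases
can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Inter-strand base-pair probabilities for a mature duplex
#'
#' Computes `P(i5 pairs with j3)` over the two arm strands of a mature
#' duplex. The built-in `"reference"` engine evaluates the partition
#' function over all non-crossing inter-strand matchings of the
#' antiparallel duplex, giving every Watson-Crick or GU wobble pair unit
#' weight and all other pairs weight zero (a McCaskill-style inside /
#' outside computation with a flat energy model). The `"vienna"` engine
#' shells out to `RNAcofold -p` from the ViennaRNA suite for
#' thermodynamic (Turner-model) probabilities and extracts the
#' inter-strand block of its pair-probability dot plot.
#'
#' @param d a [mature_duplex()].
#' @param engine `"reference"` (default, self-contained) or `"vienna"`
#'   (requires the `RNAcofold` binary on the PATH).
#' @return A matrix of pairing probabilities with rows indexing `seq5`
#'   positions and columns `seq3` positions (both 5'->3' in hairpin
#'   order); attribute `engine` records the engine and version. Row and
#'   column sums never exceed 1.
#' @export
#' @examples
#' d <- mature_duplex("toy", "GC", "GC",
#'                    data.frame(i5 = integer(0), j3 = integer(0)))
#' cofold_bpp(d)
cofold_bpp <- function(d, engine = c("reference", "vienna")) {
  stopifnot(inherits(d, "mature_duplex"))
  engine <- match.arg(engine)
  if (nchar(d$seq5) == 0 || nchar(d$seq3) == 0) {
    stop("duplex '", d$id, "': empty strand", call. = FALSE)
  }
  m <- switch(engine,
              reference = reference_bpp(d$seq5, d$seq3),
              vienna = vienna_bpp(d$seq5, d$seq3))
  dimnames(m) <- list(seq_len(nchar(d$seq5)), seq_len(nchar(d$seq3)))
  m
}

# Partition function over non-crossing matchings of X = seq5 against
# Y' = reverse(seq3) (the antiparallel duplex orientation turns the
# non-crossing condition into a monotone matching). inside[i, k] counts
# matchings of X[i..m] x Y'[k..n]; outside[i, k] counts matchings of
# X[1..i-1] x Y'[1..k-1]. P(bond i-k) = outside * pairable * inside'.
reference_bpp <- function(seq5, seq3) {
  X <- strsplit(seq5, "")[[1L]]
  Yr <- rev(strsplit(seq3, "")[[1L]])
  m <- length(X); n <- length(Yr)
  C <- outer(X, Yr, FUN = Vectorize(can_pair)) * 1

  inside <- matrix(1, m + 1L, n + 1L)
  for (i in m:1) {
    for (k in n:1) {
      inside[i, k] <- inside[i + 1L, k] +
        sum(C[i, k:n] * inside[i + 1L, (k + 1L):(n + 1L)])
    }
  }
  outside <- matrix(1, m + 1L, n + 1L)
  for (i in 2:(m + 1L)) {
    for (k in 1:(n + 1L)) {
      unpaired <- outside[i - 1L, k]
      paired <- if (k > 1L) {
        sum(C[i - 1L, 1:(k - 1L)] * outside[i - 1L, 1:(k - 1L)])
      } else 0
      outside[i, k] <- unpaired + paired
    }
  }
  Z <- inside[1L, 1L]
  P <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (k in seq_len(n)) {
      if (C[i, k] > 0) {
        P[i, k] <- outside[i, k] * inside[i + 1L, k + 1L] / Z
      }
    }
  }
  # map Y' columns back to seq3 sequence order
  P <- P[, n:1, drop = FALSE]
  structure(P, engine = "reference unit-weight partition function")
}

# RNAcofold -p engine: parse the inter-strand ubox entries of the
# pair-probability dot plot
vienna_bpp <- function(seq5, seq3) {
  exe <- Sys.which("RNAcofold")
  if (!nzchar(exe)) {
    stop("RNAcofold not found on PATH; use engine = \"reference\"",
         call. = FALSE)
  }
  m <- nchar(seq5); n <- nchar(seq3)
  wd <- tempfile("cofold")
  dir.create(wd)
  old <- setwd(wd)
  on.exit({
    setwd(old)
    unlink(wd, recursive = TRUE)
  })
  input <- paste0(">duplex\n", seq5, "&", seq3, "\n")
  out <- system2(exe, c("-p", "--noPS"), input = input, stdout = TRUE,
                 stderr = TRUE)
  dp <- file.path(wd, "duplex_dp.ps")
  if (!file.exists(dp)) {
    stop("RNAcofold produced no dot plot: ", paste(out, collapse = " "),
         call. = FALSE)
  }
  lines <- grep("ubox$", readLines(dp), value = TRUE)
  lines <- lines[grepl("^[0-9]", lines)]
  P <- matrix(0, m, n)
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    i <- as.integer(f[1L]); j <- as.integer(f[2L])
    p <- as.numeric(f[3L])^2
    if (i <= m && j > m) P[i, j - m] <- p
  }
  ver <- tryCatch(system2(exe, "--version", stdout = TRUE)[1L],
                  error = function(e) "RNAcofold")
  structure(P, engine = ver)
}

#' Per-position BPP curve on the cleavage-centered axis
#'
#' Looks up the pairing probability of each recorded bond and fills
#' positions without a recorded bond with that nucleotide's mean
#' probability over all candidate partners on the opposite strand
#' (`fill = "partner_mean"`). Positions are mapped onto the axis used for
#' duplex profiles: 5' arm positions are negative counting back from the
#' cleavage site, 3' arm positions positive, the loop-adjacent ends of the
#' arms sitting at -1 and +1 and 0 left as an empty marker between the
#' strands.
#'
#' @param m a pair-probability matrix from [cofold_bpp()].
#' @param d the [mature_duplex()] it was computed for.
#' @param fill `"partner_mean"` (computable per miRNA in isolation) or
#'   `"none"` (unrecorded positions get `NA`; used by cohort-level
#'   filling, see [hairpin_bpp_auc()]).
#' @return A `bpp_curve` data.frame with columns `position` (integer,
#'   strictly increasing, no 0), `bpp`, and `recorded` (logical).
#' @export
bpp_curve <- function(m, d, fill = c("partner_mean", "none")) {
  stopifnot(inherits(d, "mature_duplex"))
  fill <- match.arg(fill)
  n5 <- nchar(d$seq5); n3 <- nchar(d$seq3)
  if (nrow(m) != n5 || ncol(m) != n3) {
    stop("matrix dimensions do not match duplex '", d$id, "'",
         call. = FALSE)
  }
  bond5 <- rep(NA_integer_, n5)  # partner (1-based col) of each 5' pos
  if (nrow(d$bonds)) bond5[d$bonds$i5 + 1L] <- d$bonds$j3 + 1L
  bond3 <- rep(NA_integer_, n3)
  if (nrow(d$bonds)) bond3[d$bonds$j3 + 1L] <- d$bonds$i5 + 1L

  v5 <- vapply(seq_len(n5), function(i) {
    if (!is.na(bond5[i])) m[i, bond5[i]]
    else if (fill == "partner_mean") mean(m[i, ]) else NA_real_
  }, numeric(1))
  v3 <- vapply(seq_len(n3), function(j) {
    if (!is.na(bond3[j])) m[bond3[j], j]
    else if (fill == "partner_mean") mean(m[, j]) else NA_real_
  }, numeric(1))

  # 5' arm: last position abuts the loop/cleavage site -> -1
  pos5 <- -(n5:1)
  # 3' arm: first position (hairpin order) abuts the loop -> +1
  pos3 <- seq_len(n3)
  structure(
    data.frame(position = c(pos5, pos3), bpp = c(v5, v3),
               recorded = c(!is.na(bond5), !is.na(bond3))),
    class = c("bpp_curve", "data.frame"), id = d$id
  )
}

#' Area under a BPP curve
#'
#' Trapezoidal integral of pairing probability over the position axis;
#' the scalar pairing-strength score used as the TRBP/Dicer-affinity
#' proxy.
#'
#' @param curve a [bpp_curve()] with at least 2 positions.
#' @param id identifier for the output record; defaults to the curve's.
#' @return An `auc_record`: list with `id`, `auc`, `n_bonds` (recorded
#'   positions) and `n_filled`.
#' @export
bpp_auc <- function(curve, id = attr(curve, "id")) {
  stopifnot(inherits(curve, "bpp_curve"))
  if (nrow(curve) < 2L) {
    stop("AUC needs at least 2 curve positions", call. = FALSE)
  }
  if (is.unsorted(curve$position, strictly = TRUE)) {
    stop("curve positions must be strictly increasing", call. = FALSE)
  }
  x <- curve$position; y <- curve$bpp
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(id = if (is.null(id)) NA_character_ else id, auc = auc,
                 n_bonds = sum(curve$recorded),
                 n_filled = sum(!curve$recorded)),
            class = "auc_record")
}

#' Score a set of hairpins: BPP curves and AUC values
#'
#' End-to-end pipeline: extract each hairpin's mature duplex, compute
#' inter-strand pairing probabilities, build the cleavage-centered BPP
#' curve and integrate it. With `fill = "cohort_mean"`, positions without
#' a recorded bond are filled with the cohort's mean recorded probability
#' at the same axis position (falling back to the per-partner mean where
#' the cohort has no recorded value there).
#'
#' @param records list of [hairpin_record()] objects.
#' @param engine passed to [cofold_bpp()].
#' @param fill `"partner_mean"` (default) or `"cohort_mean"`.
#' @return Data frame with one row per hairpin: `id`, `auc`, `n_bonds`,
#'   `n_filled`. The curves are attached as the `"curves"` attribute
#'   (a named list of `bpp_curve` objects).
#' @export
hairpin_bpp_auc <- function(records, engine = "reference",
                            fill = c("partner_mean", "cohort_mean")) {
  fill <- match.arg(fill)
  duplexes <- lapply(records, extract_mature_duplex)
  mats <- lapply(duplexes, cofold_bpp, engine = engine)

  if (fill == "partner_mean") {
    curves <- Map(function(m, d) bpp_curve(m, d, fill = "partner_mean"),
                  mats, duplexes)
  } else {
    raw <- Map(function(m, d) bpp_curve(m, d, fill = "none"),
               mats, duplexes)
    fallback <- Map(function(m, d) bpp_curve(m, d, fill = "partner_mean"),
                    mats, duplexes)
    all_pos <- sort(unique(unlist(lapply(raw, `[[`, "position"))))
    cohort <- vapply(all_pos, function(p) {
      vals <- unlist(lapply(raw, function(cv) {
        cv$bpp[cv$position == p & cv$recorded]
      }))
      if (length(vals)) mean(vals) else NA_real_
    }, numeric(1))
    names(cohort) <- all_pos
    curves <- Map(function(cv, fb) {
      miss <- !cv$recorded
      fillv <- cohort[as.character(cv$position[miss])]
      fillv[is.na(fillv)] <- fb$bpp[miss][is.na(fillv)]
      cv$bpp[miss] <- fillv
      cv
    }, raw, fallback)
  }
  aucs <- Map(function(cv, d) bpp_auc(cv, id = d$id), curves, duplexes)
  out <- data.frame(
    id = vapply(aucs, `[[`, character(1), "id"),
    auc = vapply(aucs, `[[`, numeric(1), "auc"),
    n_bonds = vapply(aucs, `[[`, numeric(1), "n_bonds"),
    n_filled = vapply(aucs, `[[`, numeric(1), "n_filled")
  )
  names(curves) <- out$id
  attr(out, "curves") <- curves
  out
}
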