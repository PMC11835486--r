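#' A pre-miRNA hairpin with mature-arm annotations
#'
#' Validating constructor for a hairpin record: RNA sequence, dot-bracket
#' secondary structure of equal length with balanced non-crossing
#' brackets, and the positions of the mature 5' and 3' arms as 0-based
#' half-open intervals on the sequence (5' arm strictly before the 3'
#' arm, no overlap). Errors name the offending record id.
#'
#' @param id identifier.
#' @param sequence RNA string over A, C, G, U (T is accepted and converted
#'   to U).
#' @param structure dot-bracket string (`.`, `(`, `)`).
#' @param arm5,arm3 integer length-2 vectors `c(start, end)`, 0-based
#'   half-open.
#' @return An object of class `hairpin_record`.
#' @export
#' @examples
#' hairpin_record("toy", "GGGGAAAACCCC", "((((....))))",
#'                arm5 = c(0, 4), arm3 = c(8, 12))
hairpin_record <- function(id, sequence, structure, arm5, arm3) {
  fail <- function(...) {
    stop("hairpin '", id, "': ", ..., call. = FALSE)
  }
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("hairpin id must be a non-empty string", call. = FALSE)
  }
  sequence <- chartr("acgutT", "ACGUUU", sequence)
  if (grepl("[^ACGU]", sequence)) fail("sequence has non-ACGU characters")
  if (nchar(structure) != nchar(sequence)) {
    fail("structure length ", nchar(structure), " != sequence length ",
         nchar(sequence))
  }
  if (grepl("[^.()]", structure)) fail("structure has non-dot-bracket characters")
  # balancedness; pairs fall out of the same stack scan
  pairs <- dotbracket_pairs(structure, on_error = fail)
  for (nm in c("arm5", "arm3")) {
    a <- get(nm)
    if (length(a) != 2L || any(!is.finite(a)) || a[1L] < 0 ||
        a[2L] <= a[1L] || a[2L] > nchar(sequence)) {
      fail("invalid ", nm, " interval [", a[1L], ", ", a[2L], ")")
    }
  }
  if (arm5[2L] > arm3[1L]) fail("arms overlap or are out of order")
  structure(list(id = id, sequence = sequence, structure = structure,
                 arm5 = as.integer(arm5), arm3 = as.integer(arm3),
                 pairs = pairs),
            class = "hairpin_record")
}

# stack scan of a dot-bracket string; returns matrix of 0-based (i, j)
# pairs with i < j, or calls on_error
dotbracket_pairs <- function(structure, on_error = stop) {
  chars <- strsplit(structure, "")[[1L]]
  stack <- integer(0)
  out <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(chars)) {
    if (chars[k] == "(") {
      stack <- c(stack, k)
    } else if (chars[k] == ")") {
      if (!length(stack)) on_error("unbalanced brackets (extra ')')")
      out <- rbind(out, c(stack[length(stack)] - 1L, k - 1L))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) on_error("unbalanced brackets (unclosed '(')")
  colnames(out) <- c("i", "j")
  out
}

#' @export
print.hairpin_record <- function(x, ...) {
  cat(sprintf("<hairpin_record> %s (%d nt, arms [%d,%d) / [%d,%d))\n",
              x$id, nchar(x$sequence), x$arm5[1L], x$arm5[2L],
              x$arm3[1L], x$arm3[2L]))
  cat(" ", x$sequence, "\n ", x$structure, "\n")
  invisible(x)
}

#' Read / write hairpin records as TSV
#'
#' Columns: `id`, `sequence`, `structure`, `arm5_start`, `arm5_end`,
#' `arm3_start`, `arm3_end` (0-based half-open intervals). Records that
#' fail validation are excluded with a message naming the record and
#' reason (set `strict = TRUE` to error instead).
#'
#' @param path file path.
#' @param strict error on the first invalid record instead of excluding.
#' @param records a list of [hairpin_record()] (for writing).
#' @return List of [hairpin_record()] objects; excluded records are
#'   reported in the `"excluded"` attribute as a data.frame (id, reason).
#' @export
read_hairpins_tsv <- function(path, strict = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("id", "sequence", "structure", "arm5_start", "arm5_end",
            "arm3_start", "arm3_end")
  if (!all(need %in% names(df))) {
    stop("hairpin TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  excluded <- data.frame(id = character(0), reason = character(0))
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(
      hairpin_record(df$id[i], df$sequence[i], df$structure[i],
                     c(df$arm5_start[i], df$arm5_end[i]),
                     c(df$arm3_start[i], df$arm3_end[i])),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      if (strict) stop(rec)
      message("excluding record: ", conditionMessage(rec))
      excluded <- rbind(excluded,
                        data.frame(id = df$id[i],
                                   reason = conditionMessage(rec)))
    } else {
      out[[length(out) + 1L]] <- rec
    }
  }
  attr(out, "excluded") <- excluded
  out
}

#' @rdname read_hairpins_tsv
#' @export
write_hairpins_tsv <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(h) {
    data.frame(id = h$id, sequence = h$sequence, structure = h$structure,
               arm5_start = h$arm5[1L], arm5_end = h$arm5[2L],
               arm3_start = h$arm3[1L], arm3_end = h$arm3[2L])
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the mature duplex and its recorded base pairs
#'
#' Cuts the mature 5' and 3' arm substrings out of a hairpin and keeps
#' exactly those structure pairs with one end in each arm, re-indexed to
#' arm-local 0-based coordinates. An empty bond list (structure pairs only
#' within the loop or arms) is allowed and flagged via `n_bonds = 0`.
#'
#' @param h a [hairpin_record()].
#' @return A `mature_duplex`: list with `id`, `seq5`, `seq3`, and `bonds`,
#'   a data.frame of arm-local pairs (`i5`, `j3`).
#' @export
extract_mature_duplex <- function(h) {
  stopifnot(inherits(h, "hairpin_record"))
  p <- h$pairs
  in5 <- p[, "i"] >= h$arm5[1L] & p[, "i"] < h$arm5[2L]
  in3 <- p[, "j"] >= h$arm3[1L] & p[, "j"] < h$arm3[2L]
  keep <- in5 & in3
  bonds <- data.frame(i5 = p[keep, "i"] - h$arm5[1L],
                      j3 = p[keep, "j"] - h$arm3[1L])
  bonds <- bonds[order(bonds$i5), , drop = FALSE]
  rownames(bonds) <- NULL
  d <- mature_duplex(id = h$id,
                     seq5 = substr(h$sequence, h$arm5[1L] + 1L, h$arm5[2L]),
                     seq3 = substr(h$sequence, h$arm3[1L] + 1L, h$arm3[2L]),
                     bonds = bonds)
  d
}

#' Construct a mature duplex directly
#'
#' @param id identifier.
#' @param seq5,seq3 arm sequences in 5'->3' order as they appear in the
#'   hairpin.
#' @param bonds data.frame of 0-based arm-local pairs (`i5`, `j3`); within
#'   the antiparallel duplex, bonds must be non-crossing (increasing `i5`
#'   implies decreasing `j3`) and each position may appear at most once.
#' @return An object of class `mature_duplex` with field `n_bonds`.
#' @export
mature_duplex <- function(id, seq5, seq3, bonds) {
  m <- nchar(seq5); n <- nchar(seq3)
  stopifnot(is.data.frame(bonds), all(c("i5", "j3") %in% names(bonds)))
  if (nrow(bonds)) {
    if (any(bonds$i5 < 0 | bonds$i5 >= m | bonds$j3 < 0 | bonds$j3 >= n)) {
      stop("duplex '", id, "': bond index out of range", call. = FALSE)
    }
    if (anyDuplicated(bonds$i5) || anyDuplicated(bonds$j3)) {
      stop("duplex '", id, "': a position appears in more than one bond",
           call. = FALSE)
    }
    o <- order(bonds$i5)
    if (is.unsorted(rev(bonds$j3[o]), strictly = TRUE)) {
      stop("duplex '", id, "': bonds cross under the antiparallel ",
           "duplex orientation", call. = FALSE)
    }
  }
  structure(list(id = id, seq5 = seq5, seq3 = seq3, bonds = bonds,
                 n_bonds = nrow(bonds)),
            class = "mature_duplex")
}

#' @export
print.mature_duplex <- function(x, ...) {
  cat(sprintf("<mature_duplex> %s: 5' %s (%d nt) / 3' %s (%d nt), %d bonds\n",
              x$id, x$seq5, nchar(x$seq5), x$seq3, nchar(x$seq3),
              x$n_bonds))
  invisible(x)
}
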