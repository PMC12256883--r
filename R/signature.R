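# 96-channel trinucleotide mutational signatures.
#
# Channels follow the COSMIC convention: six pyrimidine-centred substitution
# classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the four 5' and four 3'
# flanking bases, ordered class-major then 5' then 3'. Purine-centred
# substitutions are reverse-complemented onto this frame before indexing.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Channel labels of the 96-channel trinucleotide signature frame
#'
#' Labels are in COSMIC order, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...,
#' `"T[T>G]T"`. Channel *i* of every [mutational_signature()] refers to
#' `signature_channels()[i]`.
#'
#' @return Character vector of length 96.
#' @export
signature_channels <- function() {
  out <- character(96)
  i <- 1L
  for (cls in SUB_CLASSES) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out[i] <- paste0(f5, "[", cls, "]", f3)
        i <- i + 1L
      }
    }
  }
  out
}

channel_index <- function(cls, f5, f3) {
  ic <- match(cls, SUB_CLASSES)
  i5 <- match(f5, BASES)
  i3 <- match(f3, BASES)
  (ic - 1L) * 16L + (i5 - 1L) * 4L + i3
}

revcomp_chars <- function(x) {
  chartr("ACGT", "TGCA", x)
}

#' Reverse complement of a nucleotide string
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(strsplit(revcomp_chars(x), ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Construct a mutational signature from channel probabilities
#'
#' A mutational signature is a probability vector over the 96
#' pyrimidine-centred substitution-in-trinucleotide-context classes. It is the
#' null model for every selection analysis in the package: the expected
#' mutation distribution of a gene is obtained by weighting each possible
#' substitution by the probability of its channel.
#'
#' @param probs Numeric vector of length 96, non-negative; normalised to sum
#'   to one. Names, if present, must equal [signature_channels()].
#' @param pseudocount Smoothing constant recorded for provenance (see
#'   [estimate_signature()]).
#' @return An object of class `mutational_signature`: a named numeric vector
#'   of 96 probabilities.
#' @seealso [estimate_signature()], [flat_signature()], [random_signature()]
#' @export
mutational_signature <- function(probs, pseudocount = 0) {
  if (length(probs) != 96L) {
    abort("a mutational signature must have exactly 96 channels")
  }
  if (any(probs < 0) || any(!is.finite(probs))) {
    abort("signature channel probabilities must be finite and non-negative")
  }
  tot <- sum(probs)
  if (tot <= 0) abort("signature probabilities must not all be zero")
  if (!is.null(names(probs)) && !identical(names(probs), signature_channels())) {
    abort("signature names must match signature_channels() in order")
  }
  out <- as.numeric(probs) / tot
  names(out) <- signature_channels()
  structure(out, pseudocount = pseudocount, class = "mutational_signature")
}

#' @export
print.mutational_signature <- function(x, ...) {
  cat("<mutational_signature> 96 channels\n")
  top <- sort(unclass(x), decreasing = TRUE)[1:5]
  cat("top channels:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn mutational_signature Uniform signature (all channels 1/96).
#' @export
flat_signature <- function() {
  mutational_signature(rep(1 / 96, 96))
}

#' Draw a random mutational signature
#'
#' Channel probabilities are drawn from a symmetric Dirichlet. Small
#' `concentration` values give spiky, realistic signatures dominated by a few
#' contexts; large values approach the flat signature.
#'
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param concentration Dirichlet concentration parameter (default 0.5).
#' @return A [mutational_signature()].
#' @export
random_signature <- function(seed, concentration = 0.5) {
  stopifnot(concentration > 0)
  g <- local_seed_eval(seed, rgamma(96, shape = concentration, rate = 1))
  mutational_signature(g / sum(g))
}

#' Tidy a mutational signature into a tibble
#'
#' @param x A `mutational_signature`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `class`, `context`, `prob`.
#' @method tidy mutational_signature
#' @export
tidy.mutational_signature <- function(x, ...) {
  lab <- signature_channels()
  tibble(
    channel = seq_len(96L),
    label = lab,
    class = stringr::str_sub(lab, 3, 5),
    context = paste0(stringr::str_sub(lab, 1, 1), stringr::str_sub(lab, 3, 3),
                     stringr::str_sub(lab, 7, 7)),
    prob = as.numeric(x)
  )
}

#' @rdname tidy.mutational_signature
#' @param object A `mutational_signature`.
#' @method autoplot mutational_signature
#' @export
autoplot.mutational_signature <- function(object, ...) {
  df <- tidy.mutational_signature(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$prob,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "trinucleotide channel", y = "probability",
                  fill = "substitution") +
    ggplot2::theme_minimal()
}

# Evaluate an expression under a local RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
local_seed_eval <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}
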