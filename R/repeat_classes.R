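#' Repeat class codes
#'
#' The annotator distinguishes four repeat classes plus an explicit
#' no-repeat label.  Class ids are used in label tracks and probability
#' matrices; id 0 is always the no-repeat class.
#'
#' * `NOREP` (0) — not repetitive
#' * `HSAT23` (1) — human satellite II/III: short, noisy tandem arrays of
#'   ATTCC-motif variants with no consistent reference unit
#' * `ALPHOID` (2) — alpha satellite: tandem arrays of ~171 bp centromeric
#'   monomers
#' * `ALU` (3) — Alu SINE, ~300 bp non-autonomous retrotransposon
#' * `LINE1` (4) — LINE-1, ~6 kb autonomous retrotransposon, frequently
#'   5'-truncated
#'
#' @format Named integer vector mapping class name to id.
#' @export
REPEAT_CLASSES <- c(NOREP = 0L, HSAT23 = 1L, ALPHOID = 2L, ALU = 3L, LINE1 = 4L)

#' Translate between repeat class ids and names
#'
#' @param id Integer vector of class ids in `0..4`.
#' @param name Character vector of class names.
#' @return `repeat_class_name()` returns class names; `repeat_class_id()`
#'   returns integer ids.
#' @export
repeat_class_name <- function(id) {
  id <- as.integer(id)
  if (any(is.na(id)) || any(id < 0L) || any(id > 4L))
    stop("repeat class id must be in 0..4")
  names(REPEAT_CLASSES)[id + 1L]
}

#' @rdname repeat_class_name
#' @export
repeat_class_id <- function(name) {
  idx <- match(toupper(name), names(REPEAT_CLASSES))
  if (any(is.na(idx)))
    stop("unknown repeat class name: ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  unname(REPEAT_CLASSES[idx])
}

# Number of true repeat classes (|C|, excluding the no-repeat label).
N_REPEAT_CLASSES <- 4L
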