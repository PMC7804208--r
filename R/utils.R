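# Internal helpers shared across modules.

# Reserved label for missing genotype calls. It contains characters that are
# illegal in VCF/PLINK genotype strings, so it cannot collide with real data.
.MISSING <- "<MISS>"

#' Missing-genotype sentinel
#'
#' Missing genotype calls are not imputed or dropped: they are kept as an
#' explicit extra genotype category (a "chaos state") that participates in
#' every downstream contingency table. This function returns the reserved
#' label used for that category.
#'
#' @return A single string, the reserved missing-genotype label.
#' @export
#' @examples
#' missing_label()
missing_label <- function() .MISSING

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never perturbs the
# user's stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 11 * as.numeric(stream)) %% 2147483647L)
}

# Stratified fold assignment: samples of each class are shuffled and dealt
# round-robin over k folds, so every fold contains both classes whenever
# each class has >= k members.
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2L)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Coerce a case/control label vector to a factor with levels
# c("control", "case"); `positive` names the state mapped to "case".
as_status <- function(values, positive = "case") {
  if (is.factor(values) && identical(levels(values), c("control", "case")))
    return(values)
  v <- as.character(values)
  if (anyNA(v)) stop("phenotype contains missing values", call. = FALSE)
  states <- unique(v)
  # Already-canonical labels pass through even when only one state (or
  # none) is present, so subsets of a labelled dataset stay valid.
  if (all(v %in% c("case", "control")) && positive == "case")
    return(factor(v, levels = c("control", "case")))
  if (length(states) != 2L)
    stop("phenotype must be binary; found states: ",
         paste(states, collapse = ", "), call. = FALSE)
  if (!positive %in% states)
    stop("positive label '", positive, "' not present in phenotype",
         call. = FALSE)
  negative <- setdiff(states, positive)
  out <- factor(ifelse(v == positive, "case", "control"),
                levels = c("control", "case"))
  attr(out, "source_labels") <- c(control = negative, case = positive)
  out
}

is_binary01 <- function(x) {
  is.numeric(x) && all(x == 0L | x == 1L)
}
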