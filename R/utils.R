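# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stopf("'%s' must be a finite number in [%s, %s]", name, format(lower), format(upper))
  invisible(x)
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a reproducible child seed from a base seed; kept within 32-bit range.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483646 + 1
}

as_gray_matrix <- function(image, name = "image") {
  if (inherits(image, "Image")) image <- EBImage::imageData(image)
  if (!is.matrix(image) || !is.numeric(image))
    stopf("'%s' must be a numeric matrix", name)
  if (any(!is.finite(image)))
    stopf("'%s' contains non-finite pixels", name)
  image
}

validate_mask <- function(mask, image = NULL, name = "mask") {
  mask <- as_gray_matrix(mask, name)
  if (!all(mask %in% c(0, 1)))
    stopf("'%s' must be binary (0/1)", name)
  if (!is.null(image) && !identical(dim(mask), dim(image)))
    stopf("incompatible mask: mask is %dx%d but image is %dx%d",
          nrow(mask), ncol(mask), nrow(image), ncol(image))
  mask
}

# Discrete disk structuring element: Euclidean distance <= radius.
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  if (r < 0L) stopf("radius must be >= 0")
  ix <- -r:r
  d2 <- outer(ix^2, ix^2, "+")
  (d2 <= radius^2) * 1
}
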