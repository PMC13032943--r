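# internal input checkers -----------------------------------------------

stop_input <- function(...) stop(..., call. = FALSE)

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_input(sprintf("'%s' must be a single probability in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop_input(sprintf("'%s' must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# binary label vector -> factor with the positive class as second level
as_binary_factor <- function(labels, positive = NULL) {
  f <- factor(labels)
  if (nlevels(f) != 2L)
    stop_input("labels must take exactly two distinct values")
  if (!is.null(positive)) {
    if (!positive %in% levels(f))
      stop_input(sprintf("positive level '%s' not found in labels", positive))
    f <- factor(f, levels = c(setdiff(levels(f), positive), positive))
  }
  f
}

positive_level <- function(f) levels(f)[2L]
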