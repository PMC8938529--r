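# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_sc <- function(msg, class) {
  rlang::abort(msg, class = c(class, "stressconcord_error"))
}

check_count_matrix <- function(x, arg = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_sc(sprintf("`%s` must be a numeric matrix (genes x samples)", arg),
             "sc_bad_input")
  }
  if (any(x < 0) || any(x != floor(x))) {
    abort_sc(sprintf("`%s` must contain non-negative integers", arg),
             "sc_bad_input")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort_sc(sprintf("`%s` must have gene rownames and sample colnames", arg),
             "sc_bad_input")
  }
  invisible(x)
}

# sample standard deviation, error-free for n >= 2 only
sample_sd <- function(x) stats::sd(x)
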