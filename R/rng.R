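# Reproducible child RNG streams.
#
# Cohort generation derives one child seed per patient/slide from a single
# root seed by stable string hashing, so a slide's content depends only on
# its identity and the root seed, never on generation order.

# FNV-1a 32-bit hash of a character tag, folded to a positive R integer.
fnv1a_hash <- function(tag) {
  bytes <- utf8ToInt(tag)
  h <- 2166136261
  for (b in bytes) {
    # xor the low byte only (b < 256); h is kept as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619, in doubles;
    # split to stay inside the 2^53 exact-integer range
    hi <- h %/% 65536; lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  as.integer(h %% 2147483647)
}

# Child seed for a labelled stream under a root seed (kept below 2^31).
child_seed <- function(root_seed, ...) {
  tag <- paste(c(root_seed, ...), collapse = "/")
  as.integer((fnv1a_hash(tag) + as.numeric(root_seed)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's global RNG state is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}
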