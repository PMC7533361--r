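# Internal helpers: local RNG scoping and a small deterministic hash.

# Evaluate expr with the RNG seeded locally, restoring (or removing) the
# global .Random.seed afterwards so the simulator never leaks random state.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# FNV-1a 32-bit over a character rendering of an R object. Used to stamp
# reports with a reproducible configuration fingerprint (no external deps).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits (h itself exceeds int range)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: h*403 < 2^41 and (h mod 2^8)*2^24 < 2^32
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
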