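# Internal helpers: 32-bit hashing for fingerprints, rounding conventions.

.MOD32 <- 2^32

# (a * b) mod 2^32 without losing precision: split a into 16-bit halves so all
# intermediate products stay below 2^53.
.mulmod32 <- function(a, b) {
    hi <- a %/% 65536
    lo <- a %% 65536
    (((hi * b) %% .MOD32) * 65536 + lo * b) %% .MOD32
}

# FNV-1a over a vector of non-negative integers (each consumed as 4 bytes).
.hash32 <- function(ints) {
    h <- 2166136261
    for (v in ints) {
        v <- v %% .MOD32
        for (shift in c(1, 256, 65536, 16777216)) {
            byte <- (v %/% shift) %% 256
            h <- .mulmod32(.xor32(h, byte), 16777619)
        }
    }
    h
}

# xor of two numbers < 2^32 via 16-bit halves (bitwXor is 32-bit signed only)
.xor32 <- function(a, b) {
    ah <- a %/% 65536; al <- a %% 65536
    bh <- b %/% 65536; bl <- b %% 65536
    bitwXor(as.integer(ah), as.integer(bh)) * 65536 +
        bitwXor(as.integer(al), as.integer(bl))
}

# round half away from zero (base round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# median with explicit midpoint convention for even n
.midpointMedian <- function(x) {
    n <- length(x)
    s <- sort(x)
    if (n %% 2L == 1L) s[(n + 1L) %/% 2L] else (s[n %/% 2L] + s[n %/% 2L + 1L]) / 2
}

.seedFrom <- function(seed, offset) as.integer((as.numeric(seed) + offset) %% 2147483647)
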