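# Shared constants (loaded first).

# flag constants
.FLAG_PAIRED <- 1L
.FLAG_PROPER <- 2L
.FLAG_UNMAPPED <- 4L
.FLAG_MATE_UNMAPPED <- 8L
.FLAG_REVERSE <- 16L
.FLAG_MATE_REVERSE <- 32L
.FLAG_FIRST <- 64L
.FLAG_SECOND <- 128L
.FLAG_DUP <- 1024L

.BASES <- c("A", "C", "G", "T")

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

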