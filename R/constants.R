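#' @keywords internal
"_PACKAGE"

# Canonical factor levels and orderings used throughout the package.
.GROUPS <- c("young", "older")
.POSITIONS <- c("up", "down", "new")
.ITEM_RESPONSES <- c("old", "new", "miss")
.SOURCE_RESPONSES <- c("up", "down", "none")
.TREES <- c("UP", "DOWN", "NEW")
.CATEGORIES <- c("old_up", "old_down", "new")
.PARAM_NAMES <- c("S_up", "S_down", "I_up", "I_down", "o", "g")
# Column order of the flattened 9-category frequency vector.
.CAT9 <- as.vector(t(outer(.TREES, .CATEGORIES, paste, sep = "/")))
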