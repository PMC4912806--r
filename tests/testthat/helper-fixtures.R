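# Phantoms are moderately expensive to build; cache them per test run.
.fixtureCache <- new.env(parent = emptyenv())

cachedPhantom <- function(placement = "island", noiseless = TRUE,
                          seed = 11) {
    key <- paste(placement, noiseless, seed, sep = "_")
    if (!exists(key, envir = .fixtureCache)) {
        cfg <- phantomConfig(placement = placement,
            lungSdHu = if (noiseless) 0 else 50,
            tissueSdHu = if (noiseless) 0 else 20, seed = seed)
        assign(key, generatePhantom(cfg), envir = .fixtureCache)
    }
    get(key, envir = .fixtureCache)
}

cachedDosePair <- function(target = 15, seed = 11) {
    key <- paste("dose", target, seed, sep = "_")
    if (!exists(key, envir = .fixtureCache)) {
        ph <- cachedPhantom("island", noiseless = FALSE, seed = seed)
        assign(key, generateDosePair(ph$structures, rx = 48,
                                     targetDeficiency = target),
               envir = .fixtureCache)
    }
    get(key, envir = .fixtureCache)
}
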