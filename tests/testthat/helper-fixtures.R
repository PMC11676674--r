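# Shared fixtures: small fields (16-cell capacity) keep image tests fast
# while exercising the full geometry of the generator.

smallShape <- c(760L, 760L)
smallPresets <- presetTable(nCellsTarget = 13L)

# draw discs/ellipses onto a flat background, on the package's 16-bit scale
drawImage <- function(shape, objects, background = 300) {
  img <- matrix(background, shape[1], shape[2])
  for (o in objects) {
    idx <- cbmnassay:::.ellipseIdx(o$r, o$c, o$a,
                                   if (is.null(o$b)) o$a else o$b,
                                   if (is.null(o$theta)) 0 else o$theta,
                                   shape)
    img[idx] <- if (is.null(o$value)) 15000 else o$value
  }
  img
}

disc <- function(r, c, radius, value = 15000)
  list(r = r, c = c, a = radius, b = radius, value = value)

# a config whose expected nucleus area matches the default presets
cfgDefault <- microscopyConfig()
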