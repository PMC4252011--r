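# Phantom geometry overrides (any argument of defaultPhantomGeometry)
bbDiameter: 4.8
halfWidth: 50
halfHeight: 50
fieldSize: [180, 180]
headMagnification: 2.5
isoMagnification: 1.5
rankFilterRank: 4
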