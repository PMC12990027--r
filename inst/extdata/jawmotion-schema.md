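# jawmotion XML motion-file schema, version 1.0

The vendor `.jawMotion` dialect is undocumented, so this package defines an
open XML dialect for time-sequenced rigid mandibular motion.  The
`.jawMotion` extension mode writes a byte-identical payload under that
extension; a vendor-specific mapping can be added as a dialect once the
vendor schema is known.

## Document structure

```xml
<?xml version="1.0" encoding="UTF-8"?>
<JawMotion schemaVersion="1.0">
  <Metadata>
    <Entry key="generator">jawmotion</Entry>
    <Entry key="frames_per_segment">100</Entry>
    <!-- arbitrary scalar entries -->
  </Metadata>
  <Frames count="607">
    <Frame index="0" time="0">
      <Matrix>1 0 0 0 0 1 0 0 0 0 1 0 0 0 0 1</Matrix>
    </Frame>
    <!-- ... -->
  </Frames>
</JawMotion>
```

## Constraints

- `schemaVersion` is mandatory; readers must reject files without it.
- `Frame/@time` is in seconds and strictly increasing across frames;
  `Frame/@index` is the 0-based frame index.
- `Matrix` holds 16 whitespace-separated numbers: a 4x4 homogeneous
  transform in **row-major** order.  The upper-left 3x3 block must be
  orthonormal with determinant +1 (a proper rotation; reflections are
  invalid), the fourth column is the translation in **millimetres**, and
  the bottom row is exactly `0 0 0 1`.
- Each matrix maps mandibular MIP-frame coordinates into the pose at that
  frame, in the fixed maxillary-anchored frame.
- Numbers are printed with 12 significant digits, so a write/read round
  trip preserves matrices within 1e-9 at the tens-of-millimetres scale of
  mandibular motion.
- At least one frame is required; zero-frame documents are invalid.
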