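# MFER-subset fixture container

`ecg2img` reads and writes a deliberately minimal tag–length–value (TLV)
binary container patterned on MFER (Medical waveform Format Encoding Rules),
so waveform fixtures can be generated, round-tripped and hand-verified
without hospital files. It is **not** interoperable with full MFER.

## File structure

```
offset 0   8 bytes   magic: ASCII "MFERSUB1"
offset 8   ...       sequence of TLV records until end of file
```

Each TLV record:

```
1 byte    tag
4 bytes   value length, unsigned little-endian
N bytes   value
```

## Tags

| tag  | name                | value encoding                       | notes |
|------|---------------------|--------------------------------------|-------|
| 0x01 | channel count       | uint16 LE                            | mandatory, before any waveform block |
| 0x02 | sampling interval   | float64 LE, seconds                  | mandatory; sampling rate = 1/interval |
| 0x03 | amplitude resolution| float64 LE, mV per integer unit      | mandatory before waveform blocks; writer default 0.001 (1 µV/LSB) |
| 0x08 | lead name           | ASCII                                | names the immediately following 0x09 block |
| 0x09 | waveform samples    | int16 LE array                       | amplitude (mV) = integer × resolution |
| 0x41 | patient id          | ASCII                                | optional |
| 0x42 | outcome label       | ASCII (`survivor`/`non_survivor`)    | optional |

Tags `0x01`–`0x3F` are *mandatory-to-understand*: a reader encountering an
unknown tag in this range fails with an unsupported-format error. Tags
`0x40`–`0xFF` are optional annotations and are skipped when unknown.

## Reader error contract

* bad magic or unknown mandatory tag → unsupported-format error
* value running past end of file → truncation error
* fewer waveform blocks than the declared channel count → truncation error
* declared channel count of zero → empty-input error

## Precision

Samples are quantised to the stored resolution when writing. Records whose
amplitudes are integer multiples of the resolution round-trip exactly;
arbitrary amplitudes round-trip to within half a resolution step (≤0.5 µV
at the default). Amplitudes beyond ±32767 resolution units do not fit int16
and raise a capacity error at write time.

## Worked byte example

A one-lead file (`II`, ten zero samples, patient `pz`, 500 Hz, default
resolution) is laid out as:

```
4D 46 45 52 53 55 42 31                    "MFERSUB1"
01 02 00 00 00 01 00                       channels = 1
02 08 00 00 00 <8-byte LE double 0.002>    interval = 1/500 s
03 08 00 00 00 <8-byte LE double 0.001>    resolution = 1e-3 mV/LSB
41 02 00 00 00 70 7A                       patient id "pz"
08 02 00 00 00 49 49                       lead name "II"
09 14 00 00 00 <20 zero bytes>             ten int16 zero samples
```

This exact layout is asserted byte-for-byte in the test suite.
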