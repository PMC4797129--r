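414249460065746469720000000103ff001c0000000c0000015000000430000000000000000000000000000000000000000000000000000000000000
000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000000
00000000000000000025004a006f009400b900de01030128014d0172019701bc01e10206022b02500275029a02bf02e40309032e03530378039d03c2
03e7040c04310456047b04a004c504ea050f05340559057e05a305c805ed06120637065c068106a606cb06f00715073a075f078407a907ce07f30818
083d0862088708ac08d108f6091b09400965098a09af09d409f90a1e0a430a680a8d0ab20ad70afc0b210b460b6b0b900bb50bda0bff0c240c490c6e
0c930cb80cdd0d020d270d4c0d710d960dbb0de00e050e2a0e4f0e740e990ebe0ee30f080f2d0f520f770f9c0fc10fe6100b10301055107a109f10c4
10e9110e11331158117d11a211c711ec12111236125b128012a512ca12ef13141339135e138300200045006a008f00b400d900fe01230148016d0192
01b701dc02010226024b0270029502ba02df03040329034e0373039803bd03e20407042c04510476049b04c004e5050a052f05540579059e05c305e8
060d06320657067c06a106c606eb07100735075a077f07a407c907ee08130838085d088208a708cc08f10916093b0960098509aa09cf09f40a190a3e
0a630a880aad0ad20af70b1c0b410b660b8b0bb00bd50bfa0c1f0c440c690c8e0cb30cd80cfd0d220d470d6c0d910db60ddb0e000e250e4a0e6f0e94
0eb90ede0f030f280f4d0f720f970fbc0fe11006102b10501075109a10bf10e41109112e11531178119d11c211e7120c12311256127b12a012c512ea
130f13341359137e001b00400065008a00af00d400f9011e01430168018d01b201d701fc02210246026b029002b502da02ff03240349036e039303b8
03dd04020427044c0471049604bb04e00505052a054f0574059905be05e30608062d06520677069c06c106e6070b07300755077a079f07c407e9080e
08330858087d08a208c708ec09110936095b098009a509ca09ef0a140a390a5e0a830aa80acd0af20b170b3c0b610b860bab0bd00bf50c1a0c3f0c64
0c890cae0cd30cf80d1d0d420d670d8c0db10dd60dfb0e200e450e6a0e8f0eb40ed90efe0f230f480f6d0f920fb70fdc10011026104b1070109510ba
10df11041129114e1173119811bd11e21207122c12511276129b12c008676f6c64656e30310673616d706c653ff00000000000003fa999999999999a
000000000000000000000000000000003fa999999999999a3ff00000000000003fa999999999999a000000000000000000000000000000003fa99999
9999999a3ff00000000000003fa999999999999a000000000000000000000000000000003fa999999999999a3ff00000000000004441544100000001
0004000200000064000000c8000000800000000044415441000000020004000200000064000000c80000014800000000444154410000000300040002
00000064000000c8000002100000000044415441000000040004000200000064000000c8000002d80000000044796523000000010004000200000001
0000000200040000000000004479654e0000000100120001000000030000000302464c00000000004479654e00000002001200010000000400000004
034a4f45000000004479654e0000000300120001000000040000000403544d52000000004479654e0000000400120001000000040000000403435852
00000000534d504c00000001001200010000000900000009000003a00000000052756e4b00000001001200010000000700000007000003a900000000
58546c6b00000001000800080000001000000080000003b000000000
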